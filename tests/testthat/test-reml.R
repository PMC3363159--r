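test_that("incidence mapping validates ids and rejects repeated records", {
  ped <- as_pedigree(data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                                dam = c(NA, NA, "B")))
  trait <- tibble::tibble(id = c("A", "B", "C"), value = 1:3)
  expect_equal(incidence_Z(ped, trait), 1:3)
  expect_error(incidence_Z(ped, tibble::tibble(id = c("A", "A"), value = 1:2)),
               "repeated")
  expect_error(incidence_Z(ped, tibble::tibble(id = "Z", value = 1)),
               "absent")
})

test_that("profiled criterion matches the dense-algebra REML oracle", {
  fx <- reml_fixture(101, n_fam = 3, prog = 2)  # n = 6 phenotyped
  idx <- incidence_Z(fx$ped, fx$trait)
  K <- fx$A[idx, idx]
  cache <- reml_spectral_cache(fx$A, idx)
  y <- fx$trait$value
  for (lam in c(0.05, 0.3, 1, 4)) {
    ll <- restricted_loglik(lam, cache, y)
    s2e <- attr(ll, "sigma_e2")
    expect_equal(as.numeric(ll),
                 as.numeric(oracle_reml_loglik(y, K, lam * s2e, s2e)),
                 tolerance = 1e-8)
  }
  expect_error(restricted_loglik(-0.1, cache, y), "non-negative")
})

test_that("lambda = 0 criterion equals the fixed-model residual likelihood", {
  fx <- reml_fixture(102, n_fam = 4, prog = 3)
  idx <- incidence_Z(fx$ped, fx$trait)
  cache <- reml_spectral_cache(fx$A, idx)
  y <- fx$trait$value
  n <- length(y)
  # closed-form REML of iid model: sigma2 = RSS/(n-1)
  rss <- sum((y - mean(y))^2)
  s2 <- rss / (n - 1)
  ll_direct <- -0.5 * ((n - 1) * log(s2) + log(n) + (n - 1) +
                         (n - 1) * log(2 * pi))
  expect_equal(as.numeric(restricted_loglik(0, cache, y)), ll_direct,
               tolerance = 1e-10)
})

test_that("criterion argmax is invariant to adding a constant to y", {
  fx <- reml_fixture(103, n_fam = 6, prog = 4)
  vc1 <- estimate_variance_components(fx$trait, fx$A, fx$ped)
  tr2 <- fx$trait
  tr2$value <- tr2$value + 100
  vc2 <- estimate_variance_components(tr2, fx$A, fx$ped)
  expect_equal(vc1$lambda, vc2$lambda, tolerance = 1e-6)
  expect_equal(vc1$sigma_a2, vc2$sigma_a2, tolerance = 1e-6)
})

test_that("spectral REML equals naive dense REML on random instances", {
  set.seed(104)
  for (rep in 1:5) {
    fx <- reml_fixture(200 + rep, n_fam = sample(4:8, 1), prog = sample(3:5, 1))
    idx <- incidence_Z(fx$ped, fx$trait)
    K <- fx$A[idx, idx]
    fit <- estimate_variance_components(fx$trait, fx$A, fx$ped)
    oracle <- oracle_reml_fit(fx$trait$value, K)
    expect_equal(fit$lambda, oracle$lambda, tolerance = 1e-3)
    expect_equal(fit$sigma_e2, oracle$sigma_e2, tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(oracle$loglik), tolerance = 1e-6)
  }
})

test_that("estimates are invariant to shuffling record order", {
  fx <- reml_fixture(105)
  vc1 <- estimate_variance_components(fx$trait, fx$A, fx$ped)
  set.seed(1)
  tr2 <- fx$trait[sample(nrow(fx$trait)), ]
  vc2 <- estimate_variance_components(tr2, fx$A, fx$ped)
  expect_equal(vc1$sigma_a2, vc2$sigma_a2, tolerance = 1e-6)
  expect_equal(vc1$sigma_e2, vc2$sigma_e2, tolerance = 1e-6)
})

test_that("null additive variance concentrates at the zero boundary", {
  # under sigma_a2 = 0 the REML estimate is a 50:50 mixture of an exact
  # zero (boundary) and a small positive half-normal deviation, so about
  # half of the replicates must sit exactly on the boundary and the rest
  # stay small
  h2s <- numeric(20)
  bound <- logical(20)
  for (rep in 1:20) {
    set.seed(300 + rep)
    ped <- reml_fixture(300 + rep, n_fam = 25, prog = 6)$ped
    A <- build_A(ped)
    prog_ids <- ped$id[!is.na(ped$sire)]
    trait <- tibble::tibble(id = prog_ids, value = rnorm(length(prog_ids)))
    vc <- estimate_variance_components(trait, A, ped)
    h2s[rep] <- vc$h2
    bound[rep] <- vc$boundary
  }
  expect_gte(sum(bound | h2s <= 0.01), 6)  # sizeable boundary mass
  expect_lte(mean(h2s), 0.10)              # and no systematic inflation
  expect_gte(sum(h2s <= 0.05), 10)
})

test_that("unrelated phenotyped individuals trigger a non-identifiability error", {
  ped <- as_pedigree(data.frame(id = sprintf("F%d", 1:40), sire = NA, dam = NA))
  A <- build_A(ped)
  trait <- tibble::tibble(id = ped$id, value = rnorm(40))
  expect_error(estimate_variance_components(trait, A, ped),
               "identifiab")
})

test_that("profile-likelihood interval covers the true ratio in moderate samples", {
  set.seed(106)
  covered <- 0L
  n_rep <- 30
  lam_true <- 0.4 / 0.6
  for (rep in seq_len(n_rep)) {
    fx <- reml_fixture(400 + rep, n_fam = 25, prog = 6, h2 = 0.4)
    fit <- estimate_variance_components(fx$trait, fx$A, fx$ped)
    ci <- reml_profile_ci(fit, fx$trait)
    if (ci["lower"] <= lam_true && lam_true <= ci["upper"]) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.80)  # 95% nominal, generous Monte-Carlo slack
})
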