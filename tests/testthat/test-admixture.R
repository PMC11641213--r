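test_that("K = 1 is degenerate: ancestry exactly 1 and a finite trace", {
  set.seed(41)
  gm <- rand_gm(n_per = 8, L = 3, k = 1, A = 3)
  fit <- fit_admixture(gm, K = 1, burn_in = 50, iterations = 200, thin = 5,
                       seed = 2)
  expect_true(all(fit$Q == 1))
  expect_true(all(is.finite(fit$loglik_trace)))
  expect_true(is.finite(fit$lnPD))
})

test_that("identical homozygotes give symmetric ancestry near 1/K", {
  gm <- gm_from_calls(matrix("1/1", nrow = 10, ncol = 2))
  fit <- fit_admixture(gm, K = 2, burn_in = 200, iterations = 2000,
                       thin = 2, seed = 3)
  expect_true(all(abs(fit$Q - 0.5) < 0.12))
})

test_that("posterior samples stay simplex-valid and the chain is seeded", {
  set.seed(44)
  gm <- rand_gm(n_per = 10, L = 4, k = 2, A = 3, missing = 0.05)
  fit <- fit_admixture(gm, K = 3, burn_in = 100, iterations = 300, thin = 5,
                       seed = 9)
  expect_equal(unname(rowSums(fit$Q)), rep(1, n_ind(gm)), tolerance = 1e-9)
  for (l in seq_len(n_loci(gm)))
    expect_equal(unname(rowSums(fit$P[[l]])), rep(1, 3), tolerance = 1e-9)
  fit2 <- fit_admixture(gm, K = 3, burn_in = 100, iterations = 300, thin = 5,
                        seed = 9)
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$loglik_trace, fit2$loglik_trace)
})

test_that("two simulated populations are recovered at K = 2", {
  p <- sim_params(c(50, 50), rep(2L, 20), fst_target = 0.3)
  set.seed(1)
  gm <- simulate_genotypes(simulate_frequencies(p), p)
  truth <- rep(1:2, each = 50)
  fit <- fit_admixture(gm, K = 2, burn_in = 500, iterations = 2000,
                       thin = 5, alpha = 0.1, seed = 101)
  hard <- apply(fit$Q, 1L, which.max)
  acc <- max(mean(hard == truth), mean(hard == 3 - truth))
  expect_gte(acc, 0.95)
  expect_gte(mean(apply(fit$Q, 1L, max)), 0.9)

  # chain-length stability: doubling burn-in moves mean Q by < 0.05
  fit_long <- fit_admixture(gm, K = 2, burn_in = 1000, iterations = 2000,
                            thin = 5, alpha = 0.1, seed = 102)
  al <- align_replicates(list(fit, fit_long))
  aligned_long <- fit_long$Q[, al$permutations[[2L]]]
  expect_lt(mean(abs(fit$Q - aligned_long)), 0.05)

  # aligned mean over two replicates preserves the assignment
  fit_b <- fit_admixture(gm, K = 2, burn_in = 500, iterations = 2000,
                         thin = 5, alpha = 0.1, seed = 103)
  avg <- align_replicates(list(fit, fit_b))$Q
  hard2 <- apply(avg, 1L, which.max)
  acc2 <- max(mean(hard2 == truth), mean(hard2 == 3 - truth))
  expect_gte(acc2, 0.95)
})

test_that("replicate alignment undoes a column permutation exactly", {
  set.seed(46)
  Q <- rdirichlet_rows_for_test(12, 3)
  mk <- function(Qm) structure(list(K = 3L, Q = Qm), class = "admixture_fit")
  perm <- c(3L, 1L, 2L)
  Qp <- Q[, perm]
  colnames(Q) <- colnames(Qp) <- paste0("K", 1:3)
  rownames(Q) <- rownames(Qp) <- paste0("A", 1:12)
  al <- align_replicates(list(mk(Q), mk(Qp)))
  expect_equal(al$Q, Q, tolerance = 1e-12)
  expect_equal(al$permutations[[2L]], order(perm))
  # single replicate returned unchanged
  al1 <- align_replicates(list(mk(Q)))
  expect_equal(al1$Q, Q)
  expect_error(align_replicates(list(mk(Q),
                                     structure(list(K = 2L, Q = Q[, 1:2]),
                                               class = "admixture_fit"))),
               "mixed K")
})

test_that("the Evanno table reproduces the hand-computed example", {
  lnpd <- list(`1` = c(-100, -100), `2` = c(-50, -50), `3` = c(-45, -45),
               `4` = c(-44, -44))
  # sd would be zero; perturb symmetrically to sd = 1 as in the worked case
  lnpd <- lapply(lnpd, function(v) v + c(-1, 1) / sqrt(2))
  ev <- evanno(lnpd)
  expect_equal(ev$Lprime, c(NA, 50, 5, 1))
  expect_equal(ev$Lsecond, c(NA, 45, 4, NA))
  expect_equal(ev$deltaK[2L], 45, tolerance = 1e-12)
  expect_equal(ev$deltaK[3L], 4, tolerance = 1e-12)
  expect_equal(attr(ev, "chosen_K"), 2L)
  # endpoints carry no deltaK
  expect_true(is.na(ev$deltaK[1L]) && is.na(ev$deltaK[4L]))
})

test_that("Evanno is shift-invariant and flags the linear/degenerate cases", {
  lnpd <- list(`2` = c(-90, -88), `3` = c(-60, -59), `4` = c(-50, -52),
               `5` = c(-48, -47))
  ev1 <- evanno(lnpd)
  ev2 <- evanno(lapply(lnpd, function(v) v + 1234))
  expect_equal(ev1$deltaK, ev2$deltaK, tolerance = 1e-9)
  expect_equal(attr(ev1, "chosen_K"), attr(ev2, "chosen_K"))
  # perfectly linear means -> all second differences zero -> ambiguous
  lin <- list(`1` = c(-30.5, -29.5), `2` = c(-20.5, -19.5),
              `3` = c(-10.5, -9.5))
  expect_warning(ev3 <- evanno(lin), "ambiguous")
  expect_true(is.na(attr(ev3, "chosen_K")))
  expect_error(evanno(list(`1` = c(-1, -2), `2` = c(-1, -2))), "at least 3")
  # zero sd at an interior K -> Inf marker with warning
  z <- list(`1` = c(-100, -99), `2` = c(-50, -50), `3` = c(-45, -44))
  expect_warning(evz <- evanno(z), "zero sd")
  expect_true(is.infinite(evz$deltaK[2L]))
})
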