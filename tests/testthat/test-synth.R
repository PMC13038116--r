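test_that("a single noiseless component yields a rank-1 video", {
  spec <- synthetic_spec(fov_shape = c(20, 20), n_frames = 300,
                         n_components = 1, noise_sigma = 0, seed = 2,
                         morphology_mix = c(soma = 1, process = 0))
  g <- generate_video(spec)
  gt <- g$ground_truth
  expect_equal(g$video$data, tcrossprod(gt$A_true, gt$Phi_true))
  # every active pixel trace is an exact scalar multiple of the trace
  act <- which(gt$A_true[, 1] > 0)
  for (i in act[1:5])
    expect_equal(g$video$data[i, ], gt$A_true[i, 1] * gt$Phi_true[, 1])
  expect_gte(length(gt$spike_times[[1]]), 1)
})

test_that("vanishing spike rate leaves near-constant baseline traces", {
  spec <- synthetic_spec(fov_shape = c(20, 20), n_frames = 200,
                         n_components = 2, spike_rate = 1e-9, noise_sigma = 0,
                         seed = 3, morphology_mix = c(soma = 1, process = 0))
  g <- generate_video(spec)
  Phi <- g$ground_truth$Phi_true
  # at most the single forced spike; the trace sits at baseline before it
  for (m in 1:2) {
    st <- g$ground_truth$spike_times[[m]]
    expect_lte(length(st), 2)
    if (min(st) > 1)
      expect_true(all(abs(Phi[seq_len(min(st) - 1), m] - Phi[1, m]) < 1e-12))
  }
})

test_that("generation is deterministic and hits the target SNR", {
  spec <- synthetic_spec(fov_shape = c(25, 25), n_frames = 512,
                         n_components = 5, seed = 11)
  g1 <- generate_video(spec)
  g2 <- generate_video(spec)
  expect_identical(g1$video$data, g2$video$data)
  # empirical pixel SNR (core pixels) within 20% of the target
  gt <- g1$ground_truth
  clean <- tcrossprod(gt$A_true, gt$Phi_true)
  core <- apply(gt$A_true, 1, max) >= 0.5
  snr_emp <- mean(apply(clean[core, ], 1, sd)) / g1$noise_sigma
  expect_lt(abs(snr_emp - spec$target_snr) / spec$target_snr, 0.2)
  # every component occupies at least one pixel and fires at least once
  expect_true(all(colSums(gt$A_true > 0) >= 1))
  expect_true(all(lengths(gt$spike_times) >= 1))
})

test_that("morphology mix produces both blobs and curvilinear processes", {
  spec <- synthetic_spec(fov_shape = c(30, 30), n_frames = 64,
                         n_components = 6, seed = 5,
                         morphology_mix = c(soma = 0.5, process = 0.5))
  g <- generate_video(spec)
  # blobs are rounder: compare support eccentricity across components
  ar <- apply(g$ground_truth$A_true, 2, function(v) {
    px <- which(v >= 0.5)
    rc <- cbind((px - 1) %/% 30 + 1, (px - 1) %% 30 + 1)
    if (nrow(rc) < 3) return(1)
    e <- eigen(cov(rc))$values
    sqrt(max(e) / max(min(e), 1e-9))
  })
  expect_gt(max(ar), 2)   # at least one elongated process
  expect_lt(min(ar), 2)   # at least one compact soma
})

test_that("match_traces tags by maximum Pearson correlation", {
  set.seed(6)
  Phi <- matrix(rnorm(8 * 5), 8, 5)
  rep_ <- match_traces(Phi, Phi)
  expect_equal(rep_$matches$ref, 1:5)
  expect_equal(rep_$matches$rho, rep(1, 5))
  # negated trace with a single reference: tagged at rho = -1
  neg <- match_traces(-Phi[, 1, drop = FALSE], Phi[, 1, drop = FALSE])
  expect_equal(neg$matches$rho, -1)
  # random fixture vs dense all-pairs oracle
  Ref <- matrix(rnorm(8 * 3), 8, 3)
  rep2 <- match_traces(Phi, Ref)
  cm <- matrix(NA_real_, 5, 3)
  for (i in 1:5) for (j in 1:3) cm[i, j] <- cor(Phi[, i], Ref[, j])
  expect_equal(rep2$cor_matrix, cm, ignore_attr = TRUE)
  expect_equal(rep2$matches$ref, apply(cm, 1, which.max))
  # permutation invariance: tags follow content, not column position
  perm <- c(3, 1, 2)
  rep3 <- match_traces(Phi, Ref[, perm])
  expect_equal(perm[rep3$matches$ref], rep2$matches$ref)
  expect_equal(rep3$matches$rho, rep2$matches$rho)
  # zero-variance trace flagged with rho 0
  flat <- cbind(Phi[, 1], rep(1, 8))
  rep4 <- match_traces(flat, Ref)
  expect_equal(rep4$flagged$est, 2L)
  expect_equal(rep4$matches$rho[2], 0)
})

test_that("agreement matrix counts matched traces per convention", {
  set.seed(7)
  base <- matrix(rnorm(50 * 4), 50, 4)
  noisy <- base + 0.1 * matrix(rnorm(50 * 4), 50, 4)
  indep <- matrix(rnorm(50 * 3), 50, 3)
  am <- agreement_matrix(list(a = base, b = noisy, c = indep))
  expect_equal(diag(am), c(a = 100, b = 100, c = 100))
  expect_equal(am["a", "b"], 100)
  expect_lt(am["a", "c"], 50)
  # identical results agree fully everywhere
  am2 <- agreement_matrix(list(base, base))
  expect_true(all(am2 == 100))
  # hand-built check of both conventions: 2 refs, 3 comparisons
  r1 <- cbind(base[, 1], base[, 2])
  r2 <- cbind(base[, 1], base[, 1] + 0.05 * rnorm(50), indep[, 1])
  ref_conv <- agreement_matrix(list(r1, r2))[1, 2]
  # ref trace 1 matches, ref trace 2 does not -> 50%
  expect_equal(ref_conv, 50)
  cmp_conv <- agreement_matrix(list(r1, r2), convention = "comparison")[1, 2]
  # two comparison traces tag ref trace 1 above 0.5 -> 2/2 refs = 100%
  expect_equal(cmp_conv, 100)
})

test_that("correlation histogram conserves counts", {
  set.seed(8)
  Phi <- matrix(rnorm(30 * 12), 30, 12)
  Ref <- matrix(rnorm(30 * 4), 30, 4)
  rep_ <- match_traces(Phi, Ref)
  h <- correlation_histogram(rep_, bin_width = 0.05)
  expect_equal(sum(h$counts), 12)
  # manual binning oracle
  manual <- table(cut(rep_$matches$rho, h$breaks, include.lowest = TRUE))
  expect_equal(h$counts, as.vector(manual))
  # all-perfect tags land in the top bin
  hp <- correlation_histogram(match_traces(Ref, Ref))
  expect_equal(hp$counts[length(hp$counts)], 4)
  expect_equal(sum(hp$counts), 4)
})
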