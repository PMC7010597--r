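# Running-sum enrichment, pairwise activation tests, per-sample activity,
# and activity correlations.

test_that("enrichment score matches the brute-force oracle exhaustively", {
  metric <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  expect_equal(enrichment_score(metric, c("g1", "g3")),
               oracle_es(metric, c("g1", "g3")), tolerance = 1e-14)

  # every subset of size 1..4 of an 8-gene universe, two weights
  set.seed(41)
  m8 <- setNames(rnorm(8), paste0("g", 1:8))
  for (k in 1:4) {
    for (idx in utils::combn(8, k, simplify = FALSE)) {
      sig <- names(m8)[idx]
      for (w in c(0, 1)) {
        expect_equal(enrichment_score(m8, sig, weight = w),
                     oracle_es(m8, sig, weight = w), tolerance = 1e-12)
      }
    }
  }
  # a top-k signature attains the running-sum maximum at position k
  topk <- names(sort(m8, decreasing = TRUE))[1:3]
  expect_gt(enrichment_score(m8, topk), 0)
  expect_error(enrichment_score(m8, names(m8)), "entire")
  expect_error(enrichment_score(m8, "absent"), "no signature gene")
})

test_that("unweighted ES is the KS statistic and is antisymmetric", {
  set.seed(42)
  metric <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  sig <- sample(names(metric), 8)
  # independent cumulative-count KS implementation
  ord <- order(-metric, names(metric))
  hits <- names(metric)[ord] %in% sig
  ks <- cumsum(hits) / sum(hits) - cumsum(!hits) / sum(!hits)
  expect_equal(enrichment_score(metric, sig, weight = 0),
               ks[which.max(abs(ks))], tolerance = 1e-12)
  # reversing the ranking negates the unweighted ES (distinct |values|)
  expect_equal(enrichment_score(-metric, sig, weight = 0),
               -enrichment_score(metric, sig, weight = 0), tolerance = 1e-12)
})

test_that("enrichment score agrees with fgsea's running-sum statistic", {
  skip_if_not_installed("fgsea")
  set.seed(45)
  m <- setNames(rnorm(60), sprintf("g%02d", 1:60))
  for (i in 1:10) {
    sig <- sample(names(m), sample(3:10, 1))
    ord <- order(-m, names(m))
    idx <- which(names(m)[ord] %in% sig)
    expect_equal(enrichment_score(m, sig, weight = 1),
                 fgsea::calcGseaStat(m[ord], idx, gseaParam = 1,
                                     scoreType = "std"),
                 tolerance = 1e-12)
  }
})

test_that("pairwise signature test calls a planted activation and only it", {
  set.seed(51)
  n <- 300
  genes <- sprintf("g%03d", seq_len(n))
  base <- rnorm(n)
  mk <- function(shift_idx) {
    m <- base + matrix(rnorm(n * 2), n)
    if (length(shift_idx)) m[shift_idx, ] <- m[shift_idx, ] + 4
    dimnames(m) <- list(genes, paste0("s", seq_len(ncol(m))))
    exp(m)
  }
  rs_A <- rank_transform(mk(integer(0)))
  rs_B <- rank_transform(mk(1:15))
  sigs <- list(up = genes[1:15], null1 = genes[101:115],
               null2 = genes[201:215])
  r <- pairwise_signature_test(rs_A, rs_B, sigs, n_perm = 400, seed = 8)
  expect_identical(r$call[r$signature == "up"], "activated")
  expect_true(all(r$call[r$signature != "up"] == "ns"))

  # identical groups: degenerate metric is flagged, everything ns, p = 1
  expect_warning(
    r0 <- pairwise_signature_test(rs_A, rs_A, sigs, n_perm = 200, seed = 9),
    "identical mean score profiles")
  expect_true(all(r0$call == "ns"))
  expect_true(all(pmin(r0$p_act, r0$p_inact) > 0.05))
  expect_warning(pairwise_signature_test(rs_A, rs_B, sigs["up"],
                                         n_perm = 50, seed = 1),
                 "one signature")
})

test_that("pairwise test p-values are calibrated under the null", {
  set.seed(61)
  n <- 200
  genes <- sprintf("g%03d", seq_len(n))
  pvals <- replicate(25, {
    mk <- function() {
      m <- matrix(rnorm(n * 2), n, dimnames = list(genes, c("a", "b")))
      exp(m)
    }
    sigs <- lapply(setNames(1:4, paste0("s", 1:4)),
                   function(i) sample(genes, 15))
    r <- pairwise_signature_test(rank_transform(mk()), rank_transform(mk()),
                                 sigs, n_perm = 99,
                                 seed = sample.int(1e6, 1))
    r$p_act
  })
  rate <- mean(pvals <= 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / length(pvals))
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("per-sample activity matches the oracle and is deterministic", {
  set.seed(71)
  x <- matrix(rexp(12), nrow = 6,
              dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  rs <- rank_transform(x)
  sigs <- list(a = c("g1", "g2", "g3"), b = c("g4", "g6"))
  act <- sample_signature_activity(rs, sigs)
  for (s in colnames(rs)) {
    for (j in names(sigs)) {
      expect_equal(act[j, s], oracle_es(rs[, s], sigs[[j]]),
                   tolerance = 1e-12)
    }
  }
  # identical samples give identical activity columns
  x2 <- cbind(x, s3 = x[, "s1"])
  act2 <- sample_signature_activity(rank_transform(x2), sigs)
  expect_equal(act2[, "s3"], act2[, "s1"])
  # a signature occupying the top of a sample's ranking maximizes ES
  top <- rownames(x)[order(-x[, "s1"])][1:2]
  acts <- sample_signature_activity(rs, list(top = top))
  expect_gt(acts["top", "s1"], 0.9)
})

test_that("group activity correlations match the closed-form Pearson", {
  act <- rbind(sig1 = c(1, 2, 2, 4, 3, 5),
               sig2 = c(2, 1, 4, 4, 6, 5),
               sig3 = c(5, 4, 3, 2, 2, 1))
  colnames(act) <- paste0("s", 1:6)
  gr <- sample_groups(list(g1 = list(samples = c("s1", "s2")),
                           g2 = list(samples = c("s3", "s4")),
                           g3 = list(samples = c("s5", "s6"))))
  r <- group_activity_correlation(act, gr)
  expect_equal(diag(r$group_cor), c(g1 = 1, g2 = 1, g3 = 1))
  # hand-computed Pearson between group-mean vectors
  m1 <- rowMeans(act[, 1:2]); m2 <- rowMeans(act[, 3:4])
  expect_equal(r$group_cor["g1", "g2"],
               sum((m1 - mean(m1)) * (m2 - mean(m2))) /
                 sqrt(sum((m1 - mean(m1))^2) * sum((m2 - mean(m2))^2)),
               tolerance = 1e-12)
  # perfectly linear activity vectors correlate at 1
  act2 <- rbind(sig1 = c(1, 2), sig2 = c(2, 4), sig3 = c(3, 6))
  colnames(act2) <- c("u", "v")
  g2 <- sample_groups(list(a = list(samples = "u"), b = list(samples = "v")))
  expect_equal(group_activity_correlation(act2, g2)$group_cor["a", "b"], 1)
  # zero-variance vector warns and yields NA
  act3 <- rbind(sig1 = c(1, 1), sig2 = c(1, 2), sig3 = c(1, 3))
  colnames(act3) <- c("u", "v")
  expect_warning(r3 <- group_activity_correlation(act3, g2), "zero-variance")
  expect_true(is.na(r3$group_cor["a", "b"]))
})
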