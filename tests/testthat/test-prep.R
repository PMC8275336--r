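# Normalization, filtering policies, smoothing and ratio construction.

mk <- function(v, features = NULL, samples = NULL) {
  m <- matrix(v, nrow = if (is.null(features)) 1 else length(features))
  rownames(m) <- features %||% sprintf("f%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("community TSS rescales columns to unit sum", {
  m <- mk(c(2, 3, 5), features = c("a", "b", "c"), samples = "s1")
  a <- community_tss(m)
  expect_equal(unname(a$values[, 1]), c(0.2, 0.3, 0.5))
  m2 <- cbind(m, s2 = c(4, 6, 10))  # scaled column gives identical result
  a2 <- community_tss(m2)
  expect_equal(unname(a2$values[, 1]), unname(a2$values[, 2]))
  expect_equal(unname(colSums(a2$values)), c(1, 1))

  bad <- mk(c(1, 2, 0, 0), features = c("a", "b"))
  expect_error(community_tss(bad), "s2")
})

test_that("within-taxon TSS normalizes features inside their species", {
  m <- mk(c(0.02, 0.06, 0.12), features = c("g1|A", "g2|A", "g3|B"))
  tx <- c("g1|A" = "A", "g2|A" = "A", "g3|B" = "B")
  w <- within_taxon_tss(m, tx)
  expect_equal(unname(w$values[, 1]), c(0.25, 0.75, 1))  # single-feature B -> 1

  # per species per sample, values sum to 1 where the species is detected
  set.seed(1)
  m2 <- matrix(rpois(60, 3), 6, 10,
               dimnames = list(sprintf("g%d|%s", 1:6, rep(c("A", "B"), 3)),
                               sprintf("s%d", 1:10)))
  tx2 <- setNames(rep(c("A", "B"), 3), rownames(m2))
  w2 <- within_taxon_tss(community_tss(m2), tx2)
  totals <- rowsum(w2$values, tx2)
  detected <- rowsum((m2 > 0) + 0, tx2) > 0
  expect_equal(unname(totals[detected]), rep(1, sum(detected)))

  expect_error(within_taxon_tss(m, c(tx[1], tx[2], NA)), "unclassified")

  # scale cancellation: within-taxon on raw counts == on community-TSS
  w_raw <- within_taxon_tss(m2, tx2)
  expect_equal(w2$values, w_raw$values)
})

test_that("taxon totals sum community abundances per species", {
  set.seed(2)
  m <- matrix(rpois(40, 5), 4, 10,
              dimnames = list(sprintf("g%d|A", 1:4), sprintf("s%d", 1:10)))
  tx <- setNames(rep("A", 4), rownames(m))
  a <- community_tss(m)
  tot <- taxon_totals(a, tx)
  expect_equal(unname(tot["A", ]), unname(colSums(a$values)))

  # partition additivity: splitting features into pseudo-species conserves sums
  tx_split <- setNames(c("A1", "A1", "A2", "A2"), rownames(m))
  tot2 <- taxon_totals(a, tx_split)
  expect_equal(unname(colSums(tot2)), unname(tot["A", ]))

  # a zero-abundance feature leaves totals unchanged
  m0 <- rbind(m, "g5|A" = 0L)
  tot3 <- taxon_totals(community_tss(m0), c(tx, "g5|A" = "A"))
  expect_equal(tot3["A", ], tot["A", ])
})

test_that("filter policies implement the lenient/semi-strict/strict rules", {
  rna <- mk(c(0, 0, 5), features = "f1")
  copy <- mk(c(0, 3, 5), features = "f1")
  expect_equal(unname(apply_filter(rna, copy, "lenient")$mask[1, ]),
               c(TRUE, TRUE, TRUE))
  expect_equal(unname(apply_filter(rna, copy, "semi-strict")$mask[1, ]),
               c(FALSE, TRUE, TRUE))
  expect_equal(unname(apply_filter(rna, copy, "strict")$mask[1, ]),
               c(FALSE, FALSE, TRUE))

  # all-zero RNA row drops the feature under every policy
  rna2 <- rbind(rna, f2 = c(0, 0, 0))
  copy2 <- rbind(copy, f2 = c(1, 1, 1))
  for (pol in c("lenient", "semi-strict", "strict")) {
    f <- apply_filter(rna2, copy2, pol)
    expect_equal(f$dropped, "f2")
    expect_false(any(f$mask["f2", ]))
  }

  # no copy estimate: strict drops RNA zeros, semi-strict keeps all samples
  expect_equal(unname(apply_filter(rna, NULL, "strict")$mask[1, ]),
               c(FALSE, FALSE, TRUE))
  expect_equal(unname(apply_filter(rna, NULL, "semi-strict")$mask[1, ]),
               c(TRUE, TRUE, TRUE))

  expect_error(apply_filter(rna, mk(c(1, 2), samples = c("x", "y"))),
               "misaligned")
})

test_that("kept cells nest strictly across policies on random matrices", {
  set.seed(3)
  for (rep in 1:5) {
    rna <- matrix(rbinom(200, 3, 0.4), 20, 10,
                  dimnames = list(sprintf("f%d", 1:20), sprintf("s%d", 1:10)))
    copy <- matrix(rbinom(200, 3, 0.4), 20, 10, dimnames = dimnames(rna))
    ml <- apply_filter(rna, copy, "lenient")$mask
    ms <- apply_filter(rna, copy, "semi-strict")$mask
    mt <- apply_filter(rna, copy, "strict")$mask
    expect_true(all(ms[mt]))  # strict-kept is semi-strict-kept
    expect_true(all(ml[ms]))  # semi-strict-kept is lenient-kept
  }
})

test_that("half-min smoothing fills zeros and preserves order", {
  a <- mtx_abund(mk(c(0, 0.2, 0.4), features = "f1"), "community-TSS")
  s <- smooth_log(a)
  expect_equal(unname(s$values[1, ]), log(c(0.1, 0.2, 0.4)))

  # feature without zeros: plain log
  b <- mtx_abund(mk(c(0.1, 0.3), features = "f1"), "community-TSS")
  expect_equal(unname(smooth_log(b)$values[1, ]), log(c(0.1, 0.3)))

  # finite on all unmasked cells; masked cells NA; order preserved
  set.seed(4)
  v <- matrix(round(runif(50), 2), 5, 10,
              dimnames = list(sprintf("f%d", 1:5), sprintf("s%d", 1:10)))
  v[v < 0.3] <- 0
  v[1, ] <- pmax(v[1, ], 0.01)
  mask <- matrix(TRUE, 5, 10, dimnames = dimnames(v))
  mask[2, 1:3] <- FALSE
  a <- mtx_abund(v, "community-TSS", mask)
  if (all(v[2, 4:10] == 0)) v[2, 4] <- 0.5  # keep the row testable
  a <- mtx_abund(v, "community-TSS", mask)
  s <- smooth_log(a)
  expect_true(all(is.finite(s$values[mask])))
  expect_true(all(is.na(s$values[!mask])))
  for (i in 1:5) {
    nz <- v[i, ] > 0 & mask[i, ]
    expect_equal(order(v[i, nz]), order(s$values[i, nz]))
  }

  # half-min computed over unmasked cells only
  v2 <- mk(c(0.5, 0.05, 0, 0.2), features = "f1")
  mask2 <- matrix(c(TRUE, FALSE, TRUE, TRUE), 1, dimnames = dimnames(v2))
  s2 <- smooth_log(mtx_abund(v2, "community-TSS", mask2))
  expect_equal(s2$values[1, 3], log(0.1))  # min over unmasked is 0.2

  # all-zero unmasked row is an error (should have been filtered)
  v3 <- mk(c(0, 0, 1), features = "f1")
  mask3 <- matrix(c(TRUE, TRUE, FALSE), 1, dimnames = dimnames(v3))
  expect_error(smooth_log(mtx_abund(v3, "community-TSS", mask3)),
               "should have been filtered")
})

test_that("log RNA/DNA ratio behaves as a homomorphism", {
  rna <- mtx_abund(mk(c(0.4, 0.1), features = "f1"), "community-TSS")
  dna <- mtx_abund(mk(c(0.1, 0.1), features = "f1"), "community-TSS")
  r <- rna_dna_log_ratio(rna, dna)
  expect_equal(r$values[1, 1], log(4))
  expect_equal(rna_dna_log_ratio(rna, rna)$values[1, ],
               setNames(c(0, 0), c("s1", "s2")))
  rna2 <- mtx_abund(mk(c(0.8, 0.2), features = "f1"), "community-TSS")
  r2 <- rna_dna_log_ratio(rna2, dna)
  expect_equal(unname(r2$values - r$values), matrix(log(2), 1, 2))
})
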