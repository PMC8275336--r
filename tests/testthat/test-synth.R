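# Community simulator: composition, pangenomes, carriage, expression,
# spiking and multinomial read sampling.

test_that("sample_composition honours prevalence and log-normal abundance", {
  tpl1 <- data.frame(species_id = "S1", prevalence = 1,
                     abund_log_mean = 0, abund_log_sd = 1e-12)
  comp <- sample_composition(tpl1, 50, seed = 1)
  expect_equal(unname(comp["S1", ]), rep(1, 50), tolerance = 1e-6)

  tpl0 <- data.frame(species_id = "S1", prevalence = 0,
                     abund_log_mean = 0, abund_log_sd = 1)
  expect_true(all(sample_composition(tpl0, 50, seed = 1) == 0))

  # Monte-Carlo: presence fraction within 3 binomial SDs of prevalence
  tpl <- data.frame(species_id = "S1", prevalence = 0.3,
                    abund_log_mean = 0, abund_log_sd = 1)
  comp <- sample_composition(tpl, 10000, seed = 42)
  phat <- mean(comp > 0)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))

  expect_error(sample_composition(data.frame(), 10), "non-empty")
})

test_that("pangenomes are uniform subsets of a shared pool", {
  pg <- build_pangenomes(c("A", "B"), pool_size = 30, genes_per_species = 30,
                         seed = 1)
  expect_equal(pg$genes$A, pg$gene_pool)  # G = P: whole pool

  pg <- build_pangenomes(c("A", "B"), pool_size = 2000,
                         genes_per_species = 1000, seed = 1)
  expect_length(pg$genes$A, 1000)
  expect_false(anyDuplicated(pg$genes$A) > 0)
  expect_true(all(pg$genes$B %in% pg$gene_pool))

  pg2 <- build_pangenomes(c("A", "B"), 2000, 1000, seed = 1)
  pg3 <- build_pangenomes(c("A", "B"), 2000, 1000, seed = 2)
  expect_identical(pg$genes, pg2$genes)
  expect_false(identical(pg$genes, pg3$genes))

  expect_error(build_pangenomes("A", 10, 11), "exceed")
})

test_that("strain carriage is Bernoulli at the carriage rate", {
  feats <- data.frame(feature_id = sprintf("g%03d|A", 1:1000),
                      gene_family = sprintf("g%03d", 1:1000), species = "A")
  car <- draw_carriage(feats, sprintf("s%d", 1:200), carriage_rate = 1,
                       seed = 1)
  expect_true(all(car))

  car <- draw_carriage(feats, sprintf("s%d", 1:1000), carriage_rate = 0.8,
                       seed = 7)
  mean_carried <- mean(colSums(car))
  expect_lt(abs(mean_carried - 800), 3 * sqrt(1000 * 0.8 * 0.2 / 1000) * sqrt(1000))
  # strains differ between samples when c < 1
  expect_false(identical(car[, 1], car[, 2]))
})

test_that("expression draws are log-normal around the reference mean", {
  feats <- data.frame(feature_id = "g1|A", gene_family = "g1", species = "A")
  car <- draw_carriage(feats, sprintf("s%d", 1:10000), 1, seed = 1)
  ex <- draw_expression(car, ref_log_mean = c("g1|A" = 0.7), sample_sd = 0)
  expect_equal(unname(ex$expr[1, ]), rep(exp(0.7), 10000))

  ex <- draw_expression(car, ref_log_mean = c("g1|A" = 0), sample_sd = 1,
                        seed = 3)
  expect_true(all(ex$expr > 0))
  expect_lt(abs(mean(log(ex$expr))), 3 / sqrt(10000))

  # not carried -> undefined
  car[1, 1] <- FALSE
  ex <- draw_expression(car, ref_log_mean = c("g1|A" = 0), seed = 1)
  expect_true(is.na(ex$expr[1, 1]))
})

test_that("spike_permute hits target rank correlations and conserves values", {
  set.seed(11)
  phen <- rep(c(0L, 1L), each = 50)
  v <- rlnorm(100)

  r0 <- spike_permute(v, phen, 0)
  expect_equal(sort(r0$values), sort(v))  # multiset conserved
  expect_lt(abs(r0$attained), 0.05 + 1e-9)

  # attainable extreme: all case values rank above control values
  r1 <- spike_permute(v, phen, 1)
  expect_false(r1$attainable)  # rho = 1 unattainable vs binary phenotype
  expect_gt(min(r1$values[phen == 1]), max(r1$values[phen == 0]))

  # Monte-Carlo: mean attained rho near 0.5 target
  att <- replicate(300, {
    spike_permute(rlnorm(100), phen, 0.5)$attained
  })
  expect_lt(abs(mean(att) - 0.5), 0.05)
  expect_equal(sort(spike_permute(v, phen, 0.5)$values), sort(v))

  # negative direction
  rn <- spike_permute(v, phen, 0.5, direction = -1)
  expect_lt(rn$attained, -0.4)

  # binary values (carriage): max attainable ~0.5 at 80% carriage, flagged
  b <- as.numeric(runif(100) < 0.8)
  rb <- spike_permute(b, phen, 0.8)
  expect_false(rb$attainable)
  expect_lt(rb$attained, 0.6)
})

test_that("simulate_counts assigns reads by species x expression weights", {
  comp <- matrix(1, 1, 3, dimnames = list("A", c("s1", "s2", "s3")))
  feats <- data.frame(feature_id = "g1|A", gene_family = "g1", species = "A")
  car <- matrix(TRUE, 1, 3, dimnames = list("g1|A", colnames(comp)))
  expr <- matrix(2.5, 1, 3, dimnames = dimnames(car))
  cm <- simulate_counts(comp, car, expr, depth = c(10L, 20L, 30L), "RNA",
                        feats$species, seed = 1)
  expect_equal(unname(cm$counts[1, ]), c(10L, 20L, 30L))  # sole gene gets all

  # two genes at 3:1 weight over many samples
  n <- 1000
  comp <- matrix(1, 1, n, dimnames = list("A", sprintf("s%d", 1:n)))
  car <- matrix(TRUE, 2, n, dimnames = list(c("g1|A", "g2|A"), colnames(comp)))
  expr <- matrix(c(3, 1), 2, n, dimnames = dimnames(car))
  depth <- rep(100L, n)
  cm <- simulate_counts(comp, car, expr, depth, "RNA", c("A", "A"), seed = 2)
  sd_mean <- sqrt(100 * 0.75 * 0.25 / n)
  expect_lt(abs(mean(cm$counts[1, ]) - 75), 3 * sd_mean)
  expect_lt(abs(mean(cm$counts[2, ]) - 25), 3 * sd_mean)

  # zero-weight sample errors
  car0 <- car; car0[, 1] <- FALSE
  expect_error(simulate_counts(comp, car0, expr, depth, "RNA", c("A", "A")),
               "zero total")
})

test_that("generated datasets conserve depth and are seed-deterministic", {
  d <- shared_dataset("null", 1001)
  expect_equal(unname(colSums(d$rna$counts)), d$metadata$depth_rna)
  expect_equal(unname(colSums(d$dna$counts)), d$metadata$depth_dna)
  expect_equal(sum(d$truth$label == "positive"), 0)
  expect_equal(nrow(d$spikes), 0)
  expect_equal(sum(d$metadata$phenotype), nrow(d$metadata) %/% 2)

  a <- do.call(make_dataset, c(list(preset = "null-bug", seed = 5), micro_args()))
  b <- do.call(make_dataset, c(list(preset = "null-bug", seed = 5), micro_args()))
  c2 <- do.call(make_dataset, c(list(preset = "null-bug", seed = 6), micro_args()))
  expect_identical(a$rna$counts, b$rna$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$rna$counts, c2$rna$counts))

  expect_error(make_dataset("no-such-preset"), "unknown preset")
})

test_that("presets spike the advertised fractions and record attained rho", {
  d <- shared_dataset("true-exp", 1001)
  npos <- sum(d$truth$label == "positive")
  expect_equal(npos, round(0.10 * nrow(d$truth)))
  pos <- d$truth[d$truth$label == "positive", ]
  expect_true(all(pos$spike_type == "expression"))
  expect_true(all(abs(pos$target_rho) == 0.8))
  # realized correlations are logged and near target where attainable
  expect_true(all(is.finite(pos$attained_rho)))
  expect_gt(mean(abs(pos$attained_rho)), 0.6)

  dm <- shared_dataset("true-exp-med", 1001)
  expect_true(all(abs(dm$truth$target_rho[dm$truth$label == "positive"]) == 0.5))

  db <- shared_dataset("null-bug", 1001)
  expect_equal(sum(db$truth$label == "positive"), 0)
  expect_equal(sum(db$spikes$spike_type == "species_abundance"),
               round(0.10 * db$params$n_species))

  dc <- shared_dataset("true-combo-bug-exp", 1001)
  expect_equal(sum(dc$truth$label == "positive"), round(0.10 * nrow(dc$truth)))
  expect_equal(sum(dc$spikes$spike_type == "species_abundance"),
               round(0.50 * dc$params$n_species))
})

test_that("orthogroup collapse sums counts, conserves reads, keeps truth", {
  d <- do.call(make_dataset, c(list(preset = "true-exp", seed = 9), micro_args()))
  g <- collapse_orthogroups(d)
  # conservation of per-sample totals
  expect_equal(colSums(g$rna$counts), colSums(d$rna$counts))
  expect_equal(colSums(g$dna$counts), colSums(d$dna$counts))
  # additivity: family total equals sum of member features
  fam <- parse_stratified_ids(rownames(d$rna$counts))$gene_family
  f1 <- rownames(g$rna$counts)[1]
  expect_equal(unname(g$rna$counts[f1, ]),
               unname(colSums(d$rna$counts[fam == f1, , drop = FALSE])))
  expect_false(g$taxonomy_known)

  # group presets come pre-collapsed with family-level truth
  dg <- shared_dataset("group-true-exp", 1001)
  expect_false(dg$taxonomy_known)
  expect_false(any(grepl("|", rownames(dg$rna$counts), fixed = TRUE)))
  expect_equal(nrow(dg$rna$counts), dg$params$pool_size)
  expect_equal(sum(dg$truth$label == "positive"),
               round(0.10 * dg$params$pool_size))
})
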