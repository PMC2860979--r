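test_that("JC closed form and its inverse are consistent", {
  expect_equal(jc_expected_p(0), 0)
  expect_equal(jc_expected_p(0.1), 0.75 * (1 - exp(-0.4 / 3)))
  expect_lt(abs(jc_expected_p(0.1) - 0.0936), 2e-4)
  expect_lte(jc_expected_p(50), 0.75)  # saturation toward 3/4
  expect_gt(jc_expected_p(5), 0.74)
  for (x in c(0.005, 0.0359, 0.15, 0.5)) {
    expect_equal(jc_expected_p(jc_divergence(x)), x)
  }
  expect_error(jc_divergence(0.8), "0.75")
  expect_error(jc_expected_p(-1), "nonnegative")
})

test_that("evolve_jc realises the expected per-site difference probability", {
  base <- paste(rep(c("A", "C", "G", "T"), 2500), collapse = "")
  expect_identical(evolve_jc(base, 0), base)

  q <- jc_expected_p(0.1)
  L <- nchar(base)
  for (method in c("exact", "bernoulli")) {
    set.seed(101)
    out <- evolve_jc(base, 0.1, method = method)
    obs <- pairwise_p(base, out)$p
    # binomial Monte-Carlo tolerance: 4 SDs of sqrt(q(1-q)/L)
    expect_lt(abs(obs - q), 4 * sqrt(q * (1 - q) / L))
  }
  # exact mode concentrates on the expectation much harder
  set.seed(5)
  out <- evolve_jc(base, 0.1, method = "exact")
  expect_lte(abs(sum(strsplit(base, "")[[1]] != strsplit(out, "")[[1]]) - L * q), 1)

  expect_error(evolve_jc("AC-T", 0.1), "gap-free")
  expect_error(evolve_jc("ACGT", -0.5), "nonnegative")
})

test_that("default study configuration encodes the four-marker design", {
  cfg <- neocalanus_config(1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(sum(cfg$group_sizes), 37L)
  expect_equal(unname(cfg$group_sizes[c("cristatus", "plumchrus",
                                        "flem_small", "flem_large")]),
               c(8L, 8L, 16L, 5L))
  expect_equal(names(cfg$locus_specs), c("COI", "12S", "ITS", "28S"))
  expect_equal(cfg$locus_specs$COI$length, 658L)
  # configured form-pair targets
  expect_equal(cfg$locus_specs$COI$between_p["flem_large", "flem_small"], 0.03586)
  expect_equal(cfg$locus_specs$`28S`$between_p["flem_large", "flem_small"], 0)
  # solved edges are nonnegative and additive consistent for the form split
  for (sp in cfg$locus_specs) expect_true(all(sp$edges_p >= 0))
})

test_that("infeasible configurations fail with a named violation", {
  bp <- function(ls, fp, fc, cp) {
    roles <- c("cristatus", "plumchrus", "flem_large", "flem_small")
    m <- matrix(0, 4, 4, dimnames = list(roles, roles))
    m["flem_large", "flem_small"] <- ls
    m["plumchrus", "flem_large"] <- m["plumchrus", "flem_small"] <- fp
    m["cristatus", "flem_large"] <- m["cristatus", "flem_small"] <- fc
    m["cristatus", "plumchrus"] <- cp
    m + t(m)
  }
  sizes <- c(cristatus = 2L, plumchrus = 2L, flem_large = 2L, flem_small = 2L)
  # forms deeper than the sibling-species split: internal edge negative
  expect_error(simulation_config(1, sizes, list(
    L = list(length = 100L, between_p = bp(0.2, 0.05, 0.21, 0.06),
             intra = 0, ambiguity_rate = 0))),
    "unrealizable")
  # between-group divergence below within-group diversity
  expect_error(simulation_config(1, sizes, list(
    L = list(length = 100L, between_p = bp(0.001, 0.05, 0.06, 0.055),
             intra = 0.01, ambiguity_rate = 0))),
    "within-group")
  # violated four-point additivity
  expect_error(simulation_config(1, sizes, list(
    L = list(length = 100L,
             between_p = local({
               m <- bp(0.02, 0.05, 0.06, 0.055)
               m["cristatus", "flem_large"] <- m["flem_large", "cristatus"] <- 0.2
               m
             }),
             intra = 0, ambiguity_rate = 0))),
    "additivity")
})

test_that("simulation is reproducible from the seed and leaves the RNG alone", {
  cfg <- neocalanus_config(7)
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_dataset(cfg)
  expect_identical(.Random.seed, before)
  s2 <- simulate_dataset(cfg)
  for (nm in names(s1$dataset$loci)) {
    expect_identical(s1$dataset$loci[[nm]]$seqs, s2$dataset$loci[[nm]]$seqs)
  }
  s3 <- simulate_dataset(neocalanus_config(8))
  expect_false(identical(s1$dataset$loci$COI$seqs, s3$dataset$loci$COI$seqs))
})

test_that("ambiguity_rate zero yields a pure ACGT alignment; positive rate injects two-fold codes", {
  cfg <- neocalanus_config(3)
  for (nm in names(cfg$locus_specs)) cfg$locus_specs[[nm]]$ambiguity_rate <- 0
  sim <- simulate_dataset(cfg)
  for (loc in sim$dataset$loci) {
    expect_true(all(loc$seqs %in% c("A", "C", "G", "T")))
  }

  cfg2 <- neocalanus_config(3)
  sim2 <- simulate_dataset(cfg2)
  chars <- unlist(lapply(sim2$dataset$loci, function(l) as.vector(l$seqs)))
  amb <- chars[!chars %in% c("A", "C", "G", "T")]
  expect_true(all(amb %in% c("R", "Y", "S", "W", "K", "M")))  # two-fold only
  # injected count concentrates around rate * total bases
  total <- length(chars)
  expect_lt(abs(length(amb) - 0.002 * total), 5 * sqrt(0.002 * total))
})

test_that("ambiguity injection removes the expected number of diagnostic columns", {
  cfg <- neocalanus_config(21)
  sim <- simulate_dataset(cfg)
  loc <- sim$dataset$loci$COI
  excl <- ambiguity_filter(loc)
  # each of L columns is hit when any of the N sequences carries a code
  rate <- cfg$locus_specs$COI$ambiguity_rate
  expect_hit <- loc$length * (1 - (1 - rate)^nrow(loc$seqs))
  expect_lt(abs(length(excl) - expect_hit), 5 * sqrt(expect_hit))
})

test_that("simulated datasets recover their configured divergence targets", {
  cfg <- neocalanus_config(11)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  summ <- all_group_summaries(ds)
  bt <- summ[summ$type == "between", ]
  key <- list(cristatus = "N. cristatus", plumchrus = "N. plumchrus",
              flem_large = "N. flemingeri|large",
              flem_small = "N. flemingeri|small")
  for (nm in names(cfg$locus_specs)) {
    bp <- cfg$locus_specs[[nm]]$between_p
    sub <- bt[bt$locus == nm, ]
    for (k in seq_len(nrow(sub))) {
      ra <- names(key)[match(sub$group_a[k], unlist(key))]
      rb <- names(key)[match(sub$group_b[k], unlist(key))]
      expect_lt(abs(sub$mean_p[k] - bp[ra, rb]), 0.01)
    }
  }
  # within-group means stay at the configured low-diversity scale
  wt <- summ[summ$type == "within", ]
  expect_true(all(wt$mean_p[wt$locus == "COI"] < 0.01))
  expect_true(all(wt$mean_p[wt$locus == "28S"] == 0))
})

test_that("simulated queries come from the requested group", {
  cfg <- neocalanus_config(4)
  sim <- simulate_dataset(cfg)
  set.seed(42)
  q <- simulate_query(sim, "COI", "cristatus")
  anc <- sim$truth$COI$ancestors$cristatus
  expect_lt(sum(q != anc) / length(q), 0.01)
  expect_error(simulate_query(sim, "nope", "cristatus"), "unknown locus")
})
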