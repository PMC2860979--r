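test_that("ambiguity filter excludes double-peak columns but not gap columns", {
  loc <- make_locus(c(s1 = "AAA", s2 = "A-G", s3 = "RAT"))
  # col 1 has R in s3 -> excluded; col 2 has a gap only -> retained;
  # col 3 is plain bases -> retained
  expect_equal(ambiguity_filter(loc), 1L)
})

test_that("variation filter requires two or more non-modal carriers", {
  loc <- make_locus(c(s1 = "AAG", s2 = "AAG", s3 = "AAT",
                      s4 = "AGT", s5 = "GGT"))
  # col1: A,A,A,A,G  -> one non-modal carrier, excluded
  # col2: A,A,A,G,G  -> two non-modal carriers, retained
  # col3: G,G,T,T,T  -> two non-modal carriers, retained
  expect_equal(variable_site_filter(loc), c(2L, 3L))
  expect_equal(variable_site_filter(loc, min_variant_carriers = 3L), integer(0))
})

test_that("gaps are ignored when counting variant carriers", {
  loc <- make_locus(c(s1 = "A", s2 = "A", s3 = "-", s4 = "G", s5 = "G"))
  expect_equal(variable_site_filter(loc), 1L)
  all_gap <- make_locus(c(s1 = "-", s2 = "-"))
  expect_equal(variable_site_filter(all_gap), integer(0))
})

test_that("classification recovers PURE and PRIVATE statuses on hand cases", {
  # col1: A,A,A | G,G,G  reciprocally fixed -> PURE for both groups
  # col2: A,A,A | A,G,G  G occurs only in B but not in all of B -> B PRIVATE
  # col3: A,A,G | G,G,G  A occurs only in A but not in all of A -> A PRIVATE,
  #                      B shares G with A -> NONE
  loc <- make_locus(c(a1 = "AAA", a2 = "AAA", a3 = "AAG",
                      b1 = "GAG", b2 = "GGG", b3 = "GGG"))
  sp <- make_specimens(c("a1", "a2", "a3", "b1", "b2", "b3"),
                       c("A", "A", "A", "B", "B", "B"))
  dt <- classify_sites(loc, sp, min_variant_carriers = 2L)
  expect_equal(dt$columns, c(1L, 2L, 3L))
  expect_equal(unname(dt$status[1, ]), c("PURE", "PURE"))
  expect_equal(unname(dt$status[2, c("A", "B")]), c("NONE", "PRIVATE"))
  expect_equal(unname(dt$status[3, c("A", "B")]), c("PRIVATE", "NONE"))
  expect_true(all(dt$informative))

  single <- make_specimens(c("a1", "a2", "a3", "b1", "b2", "b3"), rep("A", 6))
  expect_error(classify_sites(loc, single), "two groups")
})

test_that("a member breaking unanimity demotes PURE to PRIVATE at that column", {
  sp5 <- make_specimens(c("a1", "a2", "a3", "b1", "b2"),
                        c("A", "A", "A", "B", "B"))
  before <- classify_sites(make_locus(c(a1 = "A", a2 = "A", a3 = "A",
                                        b1 = "G", b2 = "G")),
                           sp5, min_variant_carriers = 1L)
  expect_equal(unname(before$status[1, ]), c("PURE", "PURE"))
  after <- classify_sites(make_locus(c(a1 = "A", a2 = "A", a3 = "T",
                                       b1 = "G", b2 = "G")),
                          sp5, min_variant_carriers = 1L)
  expect_equal(unname(after$status[1, "A"]), "PRIVATE")
  expect_equal(unname(after$status[1, "B"]), "PURE")
})

test_that("all-gap groups get empty state sets and NONE status", {
  loc <- make_locus(c(a1 = "--", a2 = "--", b1 = "AG", b2 = "GA"))
  sp <- make_specimens(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  dt <- classify_sites(loc, sp, min_variant_carriers = 1L)
  expect_equal(unname(dt$status[, "A"]), c("NONE", "NONE"))
  # B's states are private (present only in B) but not shared by all members
  expect_equal(unname(dt$status[, "B"]), c("PRIVATE", "PRIVATE"))
})

test_that("classify_sites agrees with the brute-force set-comparison oracle", {
  set.seed(31)
  for (rep in 1:120) {
    n_groups <- sample(2:4, 1)
    sizes <- sample(2:4, n_groups, replace = TRUE)
    n <- sum(sizes)
    m <- random_alignment(n, sample(5:30, 1), p_ambig = 0.08, p_gap = 0.08)
    groups <- rep(LETTERS[1:n_groups], sizes)
    sp <- make_specimens(rownames(m), groups)
    loc <- aligned_locus(m, "rand")
    dt <- classify_sites(loc, sp, min_variant_carriers = 2L)
    for (k in seq_along(dt$columns)) {
      want <- brute_classify_column(m[, dt$columns[k]], groups)
      expect_identical(unname(dt$status[k, ]), unname(want$status))
      for (g in dt$groups) {
        expect_identical(dt$state_sets[[k]][[g]], want$sets[[g]])
      }
    }
  }
})

test_that("removing a whole group never demotes another group's PURE status", {
  set.seed(57)
  for (rep in 1:40) {
    m <- random_alignment(9, 12, p_ambig = 0, p_gap = 0.05)
    groups <- rep(c("A", "B", "C"), each = 3)
    sp <- make_specimens(rownames(m), groups)
    dt3 <- classify_sites(aligned_locus(m, "L"), sp, min_variant_carriers = 1L)
    # drop group C entirely: A's and B's PURE columns must survive
    keep <- groups != "C"
    dt2 <- classify_sites(aligned_locus(m[keep, ], "L"),
                          make_specimens(rownames(m)[keep], groups[keep]),
                          min_variant_carriers = 1L)
    common <- intersect(dt3$columns, dt2$columns)
    for (cc in common) {
      for (g in c("A", "B")) {
        if (dt3$status[match(cc, dt3$columns), g] == "PURE") {
          expect_equal(unname(dt2$status[match(cc, dt2$columns), g]), "PURE")
        }
      }
    }
  }
})

test_that("pure differences count disjoint state-set columns", {
  loc <- make_locus(c(a1 = "AAAAA", a2 = "AAAAA",
                      b1 = "GGGGG", b2 = "GGGGG"))
  sp <- make_specimens(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  dt <- classify_sites(loc, sp)
  expect_equal(count_pure_differences(dt, "A", "B"), 5L)

  same <- make_locus(c(a1 = "AG", a2 = "GA", b1 = "AG", b2 = "GA"))
  dt2 <- classify_sites(same, sp)
  expect_equal(count_pure_differences(dt2, "A", "B"), 0L)
  expect_error(count_pure_differences(dt, "A", "Z"), "unknown group")
})

test_that("assignment votes only at pure columns and respects the tie rule", {
  loc <- make_locus(c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA",
                      b1 = "GGGGGGGGGG", b2 = "GGGGGGGGGG"))
  sp <- make_specimens(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  dt <- classify_sites(loc, sp)

  res <- assign_specimen("AAAAAAAAAA", dt)
  expect_equal(res$group, "A")
  expect_equal(unname(res$tally["A"]), 10L)

  tie <- assign_specimen("AAAGGGAAGG", dt)  # 5 votes each
  expect_equal(unname(tie$tally), c(5L, 5L))
  expect_equal(tie$group, "UNASSIGNED")

  allN <- assign_specimen(strrep("N", 10), dt)
  expect_equal(allN$group, "UNASSIGNED")
  expect_equal(sum(allN$tally), 0L)  # N casts no vote

  # ambiguity code votes for every group whose pure base it may contain
  amb <- assign_specimen(paste0("R", strrep("A", 9)), dt)
  expect_equal(unname(amb$tally), c(10L, 1L))  # R = A/G votes both at col 1
  expect_equal(amb$group, "A")

  expect_error(assign_specimen("AAA", dt), "shorter")
})

test_that("noiseless simulated queries are always assigned to their true form", {
  for (seed in 1:5) {
    cfg <- neocalanus_config(seed)
    sim <- simulate_dataset(cfg)
    dt <- classify_sites(sim$dataset$loci$COI, sim$dataset$specimens)
    set.seed(seed + 1000)
    for (role in c("flem_large", "flem_small")) {
      truth <- role_group(cfg, role)
      anc <- sim$truth$COI$ancestors[[role]]  # noiseless group consensus
      expect_equal(assign_specimen(anc, dt)$group, truth)
    }
  }
})

test_that("diagnostic table writer and text rendering are consistent", {
  tg <- toy_two_groups()
  dt <- classify_sites(tg$locus, tg$specimens)
  path <- tempfile(fileext = ".tsv")
  write_diag_table(dt, path)
  df <- read.delim(path)
  expect_equal(df$column, dt$columns)
  expect_true(all(c("status.A", "status.B") %in% names(df)))
  lines <- capture.output(render_diag_alignment(dt, tg$locus, tg$specimens))
  expect_length(lines, nrow(tg$locus$seqs) + 1L)
  expect_match(paste(lines, collapse = "\n"), "\\[")
})
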