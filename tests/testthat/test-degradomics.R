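test_that("aggregate_observations collapses duplicates and applies the floor", {
  rows <- dplyr::bind_rows(
    obs("AVLK", "K", "T", active = 3, control = NA),
    obs("AVLK", "K", "T", active = 5, control = NA),
    obs("GGGR", "K", "T", active = NA, control = 7))
  agg <- aggregate_observations(rows)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$abundance_active[agg$peptide == "AVLK"], 8)
  expect_true(is.na(agg$abundance_control[agg$peptide == "AVLK"]))
  expect_true(is.na(agg$abundance_active[agg$peptide == "GGGR"]))

  expect_equal(nrow(aggregate_observations(obs(character(0), character(0),
                                               character(0)))), 0)
  # zero counts as absent by default
  z <- aggregate_observations(obs("AVLK", "K", "T", active = 0, control = 2))
  expect_true(is.na(z$abundance_active))
})

test_that("compute_ratios applies the singleton convention on both scales", {
  rec <- dplyr::bind_rows(
    obs("AVLK", "K", "T", active = 200, control = 100),
    obs("GGGK", "K", "T", active = 5, control = NA),
    obs("TTTK", "K", "T", active = NA, control = 5)) |>
    aggregate_observations() |>
    compute_ratios()
  both <- rec[rec$detection_class == "both", ]
  expect_equal(both$ratio, 2)
  expect_equal(both$log2_ratio, 1)
  expect_equal(both$conv_ratio, 0.5)

  act <- rec[rec$detection_class == "active_only", ]
  expect_identical(act$ratio, 100)
  expect_equal(round(act$log2_ratio, 2), 6.64)
  expect_true(is.na(act$conv_ratio))

  ctl <- rec[rec$detection_class == "control_only", ]
  expect_identical(ctl$conv_ratio, 100)
  expect_true(is.na(ctl$ratio))

  expect_warning(
    compute_ratios(obs("AVLK", "K", "T", active = NA, control = NA)),
    "dropped")
})

test_that("z-scores come from both-group log2 ratios only", {
  # both-group log2 ratios {-2,-1,0,1,2}: sample sd 1.5811, mean 0, so a
  # singleton at log2(100) lands at z = 6.6439 / 1.5811 = 4.202
  rec <- both_group_records(c(-2, -1, 0, 1, 2),
                            extra = obs("NTVMECDACGMQQS", "K", "V", active = 77))
  rec <- compute_zscores(rec)
  singleton <- rec[rec$detection_class == "active_only", ]
  expect_equal(singleton$z, 4.201944, tolerance = 1e-6)
  stats <- attr(rec, "scale_stats")
  expect_equal(stats$mean_log2[1], 0)
  expect_equal(stats$sd_log2[1], 1.581139, tolerance = 1e-6)

  # population-sd option divides by n rather than n-1
  pop <- compute_zscores(rec, sd_type = "population")
  expect_equal(attr(pop, "scale_stats")$sd_log2[1],
               1.581139 * sqrt(4 / 5), tolerance = 1e-6)

  expect_error(compute_zscores(both_group_records(c(1, 1, 1))),
               "degenerate")
  expect_error(compute_zscores(both_group_records(numeric(0),
                                                  extra = obs("AK", "K", "T", active = 1))),
               ">= 2 both-group")
})

test_that("z is an affine function of the log2 ratio within a run", {
  withr::with_seed(11, {
    rec <- compute_zscores(both_group_records(rnorm(30, 0, 1.5)))
    s <- attr(rec, "scale_stats")$sd_log2[1]
    i <- seq_len(nrow(rec) - 1)
    expect_equal((rec$z[i] - rec$z[i + 1]) * s,
                 rec$log2_ratio[i] - rec$log2_ratio[i + 1])
  })
})

test_that("select_candidates keeps singletons and significant both-group semis", {
  extra <- dplyr::bind_rows(
    obs("GAVLNT", "K", "T", active = 3),                  # semi singleton, low abundance
    obs("TAVLNT", "K", "T", active = 2e5, control = 1e5), # semi, z modest
    obs("SAVLNT", "K", "T", active = 5e7, control = 1e5), # semi, z large
    obs("GGNTGG", "T", "T", active = 4),                  # non-tryptic singleton
    obs("CAVLNT", "K", "T", active = NA, control = 10))   # semi, control-only
  rec <- compute_zscores(both_group_records(c(-1.5, -0.5, 0, 0.5, 1.5), extra))
  sel <- select_candidates(rec, z_threshold = 2)
  expect_setequal(sel$peptide, c("GAVLNT", "SAVLNT"))
  expect_true(all(sel$tryptic_status == "semi"))
  expect_equal(attr(sel, "flagged_nontryptic")$peptide, "GGNTGG")
  expect_equal(attr(sel, "unexplained_control")$peptide, "CAVLNT")

  # strict threshold: z must exceed, not reach
  z24 <- rec[rec$peptide == "TAVLNT", ]$z
  expect_lt(z24, 2)
})

test_that("call_cleavage_sites derives P1 from the non-tryptic terminus", {
  protein <- scaffold_protein()
  extra <- dplyr::bind_rows(
    obs("NTVMECDACGMQQS", "K", "V", active = 10),             # C-term boundary: S77
    obs("SVRTGLPSVRPLLHCAPGFCFPGVACIQTESGAR", "Q", "C", active = 9),  # N-term: Q76
    obs("EITFLKNTVMECDACGMQQS", "R", "V", active = 8),        # duplicate boundary S77
    obs("AVKSSTGPGEQLRNALWHTGDTESQVR", "K", "L", active = 7)) # fully tryptic: rejected
  rec <- compute_zscores(both_group_records(c(-1, -0.3, 0.2, 1), extra))
  cand <- select_candidates(rec)
  sites <- call_cleavage_sites(cand, protein)
  expect_equal(sites$p1_pos, c(76L, 77L))
  expect_equal(sites$p1, c("Q", "S"))
  expect_equal(sites$p1prime, c("S", "V"))
  expect_equal(sites$n_semi, c(1, 2))
  # every supporting peptide's non-tryptic terminus coincides with the boundary
  for (i in seq_len(nrow(sites))) {
    ev <- sites$evidence[[i]]
    at_boundary <- ifelse(ev$boundary_side == "n", ev$start - 1L, ev$end)
    expect_true(all(at_boundary == sites$p1_pos[i]))
  }

  # a peptide abutting the protein terminus is non-evidentiary, never a site
  term <- classify_termini(obs("EAASR", "-", "T", active = 5)) |>
    dplyr::mutate(detection_class = "active_only", ratio = 100,
                  log2_ratio = log2(100), z = NA_real_)
  expect_equal(nrow(call_cleavage_sites(term, "EAASRTSNL")), 0)

  # unlocalizable candidates are skipped with a warning
  ghost <- classify_termini(obs("WWWWHHHH", "K", "T", active = 5)) |>
    dplyr::mutate(detection_class = "active_only", ratio = 100,
                  log2_ratio = log2(100), z = NA_real_)
  expect_warning(out <- call_cleavage_sites(ghost, protein), "not found")
  expect_equal(nrow(out), 0)
})

test_that("spanning evidence requires strict containment of the boundary", {
  protein <- scaffold_protein()
  extra <- dplyr::bind_rows(
    obs("NTVMECDACGMQQS", "K", "V", active = 10),                  # site S77
    obs("EITFLKNTVMECDACGMQQSVR", "R", "T", active = NA, control = 9), # spans 58-79
    obs("QQVREITFLKNTVMECDACGMQQS", "R", "V", active = 11))
  # NTVMECDACGMQQSVR (64-79) is in the both-group background via the digest;
  # build an explicit tryptic peptide ending exactly at P1 = 77: none exists
  # among tryptic peptides, so test the rule directly with a peptide whose
  # span ends at 77 -- use find_spanning_evidence on constructed records.
  rec <- compute_zscores(both_group_records(c(-1, 0, 0.4, 1), extra))
  cand <- select_candidates(rec)
  sites <- call_cleavage_sites(cand, protein) |>
    find_spanning_evidence(rec, protein)
  s77 <- sites[sites$p1_pos == 77, ]
  expect_equal(s77$n_spanning, 1)
  expect_equal(s77$spanning[[1]]$peptide, "EITFLKNTVMECDACGMQQSVR")
  expect_true(s77$spanning[[1]]$corroborating)  # control-only

  # boundary case: a fully tryptic record ending exactly at P1 does not span
  edge <- dplyr::bind_rows(
    obs("NTVMECDACGMQQS", "K", "V", active = 10),
    obs("EITFLK", "R", "N", active = NA, control = 3))  # span 58-63, ends before
  rec2 <- compute_zscores(both_group_records(c(-0.5, 0, 0.5), edge))
  sites2 <- call_cleavage_sites(select_candidates(rec2), protein) |>
    find_spanning_evidence(rec2, protein)
  expect_equal(sites2$n_spanning, 0)   # no spanning evidence, site retained
  expect_equal(sites2$p1_pos, 77L)
})

test_that("compare_site_sets intersects on substrate and P1 position", {
  a <- tibble::tibble(accession = "X", p1_pos = c(10L, 20L, 30L),
                      p1 = "A", p1prime = "G")
  b <- tibble::tibble(accession = "X", p1_pos = c(20L, 40L),
                      p1 = "A", p1prime = "G")
  cmp <- compare_site_sets(a, b)
  expect_equal(cmp$shared$p1_pos, 20L)
  expect_equal(cmp$only_a$p1_pos, c(10L, 30L))
  expect_equal(cmp$only_b$p1_pos, 40L)

  same <- compare_site_sets(a, a)
  expect_equal(nrow(same$shared), 3)
  expect_equal(nrow(same$only_a), 0)

  disjoint <- compare_site_sets(a, dplyr::mutate(b, p1_pos = p1_pos + 1L))
  expect_equal(nrow(disjoint$shared), 0)

  expect_error(compare_site_sets(a, dplyr::mutate(b, accession = "Y")),
               "different substrates")
})

test_that("the caller agrees with an independent brute-force boundary check", {
  for (seed in 1:4) {
    sim <- simulate_degradome(seed = seed, noise_sd = 1, n_sites = 4)
    called <- call_sites(sim$quant, sim$substrate)$sites$p1_pos
    brute <- brute_force_sites(sim$quant, sim$substrate$sequence)
    expect_equal(sort(called), brute)
  }
})
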