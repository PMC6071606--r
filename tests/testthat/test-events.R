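L1 <- "loss_of_parent1_allele"
G1 <- "gain_of_parent1_allele"
G2 <- "gain_of_parent2_allele"
B <- "balanced"
U <- "unknown"

test_that("find_aberrant_runs enforces the 3-consecutive rule", {
  pos <- function(n) seq_len(n) * 1000
  ## two linked losses are not enough
  expect_identical(nrow(find_aberrant_runs(c(L1, L1, B, B, B), pos(5))), 0L)
  r <- find_aberrant_runs(c(B, L1, L1, L1, B), pos(5))
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_support, 3L)
  expect_identical(r$direction, "loss")
  expect_identical(r$parent_of_origin, "parent1")
  ## 12 losses with one interior no-call still form one run of support 12
  v <- c(rep(L1, 6), U, rep(L1, 6))
  r2 <- find_aberrant_runs(v, pos(13))
  expect_identical(r2$n_support, 12L)
  expect_identical(c(r2$start, r2$end), c(1000, 13000))
  ## a second interior no-call exceeds the default tolerance
  v3 <- c(rep(L1, 4), U, rep(L1, 4), U, rep(L1, 4))
  expect_identical(nrow(find_aberrant_runs(v3, pos(14))), 2L)
  ## balanced or opposing calls always break runs
  expect_identical(nrow(find_aberrant_runs(c(L1, L1, B, L1, L1), pos(5))),
                   0L)
  expect_identical(nrow(find_aberrant_runs(c(L1, L1, G1, L1, L1), pos(5))),
                   0L)
  ## runs are per parent of origin
  r4 <- find_aberrant_runs(c(rep(G1, 3), rep(G2, 3)), pos(6))
  expect_identical(sort(r4$parent_of_origin), c("parent1", "parent2"))
  expect_error(find_aberrant_runs(c(L1, L1, L1), c(3, 2, 1)), "sorted")
})

test_that("run finding equals the brute-force oracle on random vectors", {
  symbols <- c(G1, G2, L1, "loss_of_parent2_allele", B, U)
  set.seed(42)
  for (i in 1:400) {
    n <- sample(1:12, 1L)
    v <- sample(symbols, n, replace = TRUE)
    pos <- cumsum(sample.int(5000, n, replace = TRUE))
    for (gt in 0:2) {
      got <- find_aberrant_runs(v, pos, min_run = 3L, gap_tolerance = gt)
      want <- oracle_find_runs(v, pos, min_run = 3L, gap_tolerance = gt)
      expect_identical(run_key(got), run_key(want))
    }
  }
})

toy_map <- data.table::data.table(
  block_id = "b1", a_chrom = "A1", a_start = 1, a_end = 2e7,
  c_chrom = "C1", c_start = 1, c_end = 4e7, orientation = "same",
  n_probes = 100L)

run_row <- function(chrom, s, e, dir, par = "parent1", n = 12L,
                    ind = "F1_001") {
  data.table::data.table(individual_id = ind, chromosome = chrom,
                         direction = dir, parent_of_origin = par,
                         start = s, end = e, first_index = 1L,
                         last_index = n, n_support = n)
}

test_that("reciprocal gain/loss runs pair into HeR; leftovers classify", {
  runs <- rbind(run_row("C1", 1e5, 5e6, "loss"),
                run_row("A1", 1e5, 3e6, "gain"))
  ev <- match_reciprocal(runs, toy_map)
  expect_identical(ev$type, "her")
  expect_identical(ev$gain_chrom, "A1")
  expect_identical(ev$loss_chrom, "C1")
  expect_identical(ev$parent_of_origin, "parent1")
  ## mismatched parent of origin blocks pairing
  runs2 <- rbind(run_row("C1", 1e5, 5e6, "loss", par = "parent1"),
                 run_row("A1", 1e5, 3e6, "gain", par = "parent2"))
  expect_setequal(match_reciprocal(runs2, toy_map)$type,
                  c("deletion", "duplication"))
  ## unpaired runs become deletion / duplication events
  expect_identical(match_reciprocal(run_row("C1", 1e5, 5e6, "loss"),
                                    toy_map)$type, "deletion")
  expect_identical(match_reciprocal(run_row("A1", 1e5, 3e6, "gain"),
                                    toy_map)$type, "duplication")
  ## non-overlapping projections do not pair
  runs3 <- rbind(run_row("C1", 3e7, 4e7, "loss"),
                 run_row("A1", 1e5, 3e6, "gain"))
  expect_setequal(match_reciprocal(runs3, toy_map)$type,
                  c("deletion", "duplication"))
  ## each run participates in at most one HeR; ambiguity is flagged
  runs4 <- rbind(run_row("C1", 1e5, 8e6, "loss"),
                 run_row("A1", 1e5, 2e6, "gain"),
                 run_row("A1", 2.5e6, 4e6, "gain"))
  ev4 <- match_reciprocal(runs4, toy_map)
  expect_identical(sum(ev4$type == "her"), 1L)
  expect_identical(sum(ev4$type == "duplication"), 1L)
  expect_true(any(ev4$flagged[ev4$type == "her"]))
  ## support below the minimum on either side blocks an HeR call
  runs5 <- rbind(run_row("C1", 1e5, 5e6, "loss", n = 2L),
                 run_row("A1", 1e5, 3e6, "gain"))
  expect_false("her" %in% match_reciprocal(runs5, toy_map,
                                           min_support = 3L)$type)
})

test_that("whole-chromosome runs become aneuploidy and leave pairing", {
  ic <- data.table::data.table(chromosome = c("A8", "C1"),
                               n_informative = c(100L, 200L))
  runs <- rbind(run_row("A8", 1e3, 2.1e7, "gain", n = 100L),
                run_row("C1", 1e5, 1.6e7, "loss", n = 80L))
  res <- detect_aneuploidy(runs, ic)
  expect_identical(res$aneuploid$chromosome, "A8")
  expect_identical(res$segmental$chromosome, "C1")
  ## 40% coverage stays segmental
  res2 <- detect_aneuploidy(run_row("C1", 1e5, 1.6e7, "loss", n = 80L), ic)
  expect_identical(nrow(res2$aneuploid), 0L)
  ## fragmented whole-chromosome coverage is judged on combined support
  frag <- rbind(run_row("A8", 1e3, 1e7, "gain", n = 60L),
                run_row("A8", 1.1e7, 2.1e7, "gain", n = 38L))
  res3 <- detect_aneuploidy(frag, ic)
  expect_identical(nrow(res3$aneuploid), 1L)
  expect_identical(res3$aneuploid$n_support, 98L)
  ## one individual may be aneuploid for several chromosomes
  two <- rbind(run_row("A8", 1e3, 2.1e7, "gain", n = 100L),
               run_row("C1", 1e3, 4.5e7, "gain", n = 195L))
  expect_identical(nrow(detect_aneuploidy(two, ic)$aneuploid), 2L)
})

test_that("inheritance classification follows population sharing", {
  base <- data.table::data.table(
    type = "deletion", gain_chrom = NA_character_, gain_start = NA_real_,
    gain_end = NA_real_, n_support_gain = NA_integer_, loss_chrom = "C1",
    loss_start = 1e6, loss_end = 5e6, n_support_loss = 20L,
    parent_of_origin = "parent1", individual_id = "F1_001", flagged = FALSE)
  one <- classify_inheritance(base, population_size = 48)
  expect_identical(one$inheritance, "de_novo")
  ten <- data.table::rbindlist(lapply(1:10, function(i) {
    x <- data.table::copy(base); x$individual_id <- sprintf("F1_%03d", i); x
  }))
  expect_identical(unique(classify_inheritance(ten, 48)$inheritance),
                   "segregating")
  all48 <- data.table::rbindlist(lapply(1:48, function(i) {
    x <- data.table::copy(base); x$individual_id <- sprintf("F1_%03d", i); x
  }))
  expect_identical(unique(classify_inheritance(all48, 48)$inheritance),
                   "fixed")
  ## events below reciprocal overlap 0.5 are different events
  far <- data.table::copy(base)
  far$individual_id <- "F1_002"; far$loss_start <- 4.5e6
  far$loss_end <- 2e7
  both <- classify_inheritance(rbind(base, far), 48)
  expect_identical(both$inheritance, c("de_novo", "de_novo"))
  expect_identical(classify_inheritance(base, 1)$inheritance,
                   "unclassified")
})

test_that("breakpoint intervals match a linear-scan oracle", {
  ## the classic tight case: flanking marker 172 bp beyond the last
  ## affected probe
  bp <- breakpoint_interval(5e5, 1e6, c(4.9e5, 5e5, 1e6, 1000172),
                            c(TRUE, FALSE, FALSE, TRUE), 2e6)
  expect_equal(bp$right, c(1e6, 1000172))
  expect_equal(diff(bp$right), 172)
  ## a run reaching the last probe extends to the chromosome end
  bp2 <- breakpoint_interval(5e5, 1e6, c(4.9e5, 5e5, 1e6),
                             c(TRUE, FALSE, FALSE), 2e6)
  expect_equal(bp2$right, c(1e6, 2e6))
  set.seed(9)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    positions <- sort(sample.int(1e7, n))
    ok <- runif(n) < 0.6
    k <- sort(sample(n, 2))
    s <- positions[k[1]]; e <- positions[k[2]]
    ok[k[1]:k[2]] <- FALSE
    got <- breakpoint_interval(s, e, positions, ok, 2e7)
    want <- oracle_breakpoint(s, e, positions, ok, 2e7)
    expect_equal(got, want)
  }
})

test_that("centromere annotation distinguishes spans and breakpoints", {
  model <- data.table::data.table(chromosome = "A1", length = 3e7,
                                  centromere_start = 14.8e6,
                                  centromere_end = 15.2e6)
  expect_identical(annotate_centromere(1e7, 2e7, model), "spans")
  ## region edge 0.4 Mb from the centromere: breakpoint at centromere
  expect_identical(annotate_centromere(1e6, 14.4e6, model),
                   "breakpoint_at_centromere")
  expect_identical(annotate_centromere(1e6, 5e6, model), "none")
  ## spans takes precedence over proximity
  expect_identical(annotate_centromere(14.7e6, 15.3e6, model), "spans")
})

test_that("detected event sets conserve HeR gain/loss and exclusivity", {
  for (seed in c(55, 56)) {
    pop <- simulate_population(sim_config(
      seed = seed, n_individuals = 10,
      marker_map = default_marker_map(150), theta_noise_sd = 0.02))
    ev <- run_pipeline(pop)
    her <- ev[ev$type == "her", ]
    ## every HeR carries exactly one gain and one loss region
    expect_true(all(!is.na(her$gain_chrom) & !is.na(her$loss_chrom)))
    expect_identical(sum(!is.na(her$gain_chrom)),
                     sum(!is.na(her$loss_chrom)))
    ## aneuploid chromosomes never re-appear as segmental events of the
    ## same individual and direction
    aneu <- ev[grepl("aneuploid", ev$type), ]
    for (i in seq_len(nrow(aneu))) {
      chrom <- ifelse(is.na(aneu$gain_chrom[i]), aneu$loss_chrom[i],
                      aneu$gain_chrom[i])
      seg <- ev[!grepl("aneuploid", ev$type) &
                  ev$individual_id == aneu$individual_id[i], ]
      expect_false(any(seg$gain_chrom %in% chrom & !is.na(seg$gain_chrom) &
                         !is.na(aneu$gain_chrom[i])))
    }
  }
})

test_that("event tables round-trip losslessly and export to BED", {
  pop <- simulate_population(sim_config(
    seed = 77, n_individuals = 8, marker_map = default_marker_map(150)))
  ev <- run_pipeline(pop)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, f)
  back <- read_events_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(ev))
  bed <- tempfile(fileext = ".bed")
  write_events_bed(ev, bed)
  rows <- read.delim(bed, header = FALSE)
  want_rows <- sum(!is.na(ev$gain_chrom)) + sum(!is.na(ev$loss_chrom))
  expect_identical(nrow(rows), want_rows)
  expect_true(all(rows$V3 > rows$V2))
})
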