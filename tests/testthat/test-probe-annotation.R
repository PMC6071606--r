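test_that("classify_specificity applies the strict >90%/<=90% rule", {
  hit <- function(sg, id, chrom = paste0(sg, "1"), pos = 100L) {
    data.frame(probe_id = "p", subgenome = sg, chromosome = chrom,
               position = pos, identity = id, stringsAsFactors = FALSE)
  }
  expect_identical(classify_specificity(rbind(hit("A", 0.95),
                                              hit("C", 0.80))),
                   "A_specific")
  expect_identical(classify_specificity(rbind(hit("A", 0.95),
                                              hit("C", 0.92))), "dual")
  expect_identical(classify_specificity(hit("A", 0.88)), "unassigned")
  ## a hit at exactly the threshold does not exceed it
  expect_identical(classify_specificity(rbind(hit("A", 0.90),
                                              hit("C", 0.50))),
                   "unassigned")
  expect_identical(classify_specificity(hit("C", 0.99)), "C_specific")
  expect_identical(classify_specificity(hit("A", 0.95)[0, ]), "unassigned")
  expect_error(classify_specificity(hit("A", 1.2)), "identity")
})

test_that("annotate_probes assigns homoeologous loci at the 50% rule", {
  hits <- data.frame(
    probe_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p4"),
    subgenome = c("A", "C", "A", "C", "A", "C", "A"),
    chromosome = c("A1", "C1", "A2", "C2", "A3", "C3", "A4"),
    position = c(100L, 1500000L, 200L, 900L, 300L, 50L, 400L),
    identity = c(0.95, 0.60, 0.95, 0.40, 0.95, 0.92, 0.88),
    stringsAsFactors = FALSE
  )
  ann <- annotate_probes(hits)
  ann <- ann[match(c("p1", "p2", "p3", "p4"), ann$probe_id), ]
  expect_identical(ann$specificity,
                   c("A_specific", "A_specific", "dual", "unassigned"))
  ## p1: C identity 0.60 >= 0.50 -> paired locus at C1:1,500,000
  expect_identical(ann$homoeo_chrom[1L], "C1")
  expect_identical(ann$homoeo_pos[1L], 1500000L)
  ## p2: 0.40 < 0.50 -> no homoeologous locus
  expect_true(is.na(ann$homoeo_chrom[2L]))
  ## dual and unassigned probes carry no loci at all
  expect_true(all(is.na(ann$primary_chrom[3:4])))
})

test_that("specificity and pairing thresholds are monotone", {
  set.seed(11)
  hits <- data.frame(
    probe_id = rep(sprintf("p%03d", 1:60), each = 2),
    subgenome = rep(c("A", "C"), 60),
    chromosome = rep(c("A1", "C1"), 60),
    position = sample.int(1e6, 120, replace = TRUE),
    identity = round(runif(120, 0.3, 1), 3),
    stringsAsFactors = FALSE
  )
  lo <- annotate_probes(hits, high_thresh = 0.80, min_identity = 0.40)
  hi <- annotate_probes(hits, high_thresh = 0.95, min_identity = 0.70)
  lo <- lo[order(lo$probe_id)]; hi <- hi[order(hi$probe_id)]
  ## raising high_thresh never converts unassigned -> specific
  was_unassigned <- lo$specificity == "unassigned"
  expect_false(any(hi$specificity[was_unassigned] %in%
                     c("A_specific", "C_specific", "dual")))
  ## raising min_identity never adds homoeologous loci
  expect_false(any(is.na(lo$homoeo_pos) & !is.na(hi$homoeo_pos) &
                     lo$specificity == hi$specificity))
})

make_loci <- function(primary_chrom, primary_pos, homoeo_chrom,
                      homoeo_pos) {
  data.frame(probe_id = sprintf("p%04d", seq_along(primary_pos)),
             specificity = "A_specific",
             primary_chrom = primary_chrom,
             primary_pos = as.integer(primary_pos),
             homoeo_chrom = homoeo_chrom,
             homoeo_pos = as.integer(homoeo_pos),
             homoeo_identity = 0.7, stringsAsFactors = FALSE)
}

test_that("collinear probes form a single block; A9/A10 split C9", {
  loci <- make_loci("A1", seq(1e5, 1e7, length.out = 100), "C1",
                    seq(2e5, 1.2e7, length.out = 100))
  map <- build_homoeology_map(loci)
  expect_identical(nrow(map), 1L)
  expect_identical(map$orientation, "same")
  expect_identical(map$n_probes, 100L)
  ## anti-collinear partner positions give an inverted block
  inv <- build_homoeology_map(
    make_loci("A2", seq(1e5, 1e7, length.out = 50), "C2",
              seq(1.2e7, 2e5, length.out = 50)))
  expect_identical(inv$orientation, "inverted")
  ## A9 pairs the top of C9 and A10 the bottom: two blocks, one partner
  split <- rbind(
    make_loci("A9", seq(1e5, 2e7, length.out = 60), "C9",
              seq(1e5, 2e7, length.out = 60)),
    make_loci("A10", seq(1e5, 1.7e7, length.out = 60), "C9",
              seq(2.05e7, 5.6e7, length.out = 60)))
  map2 <- build_homoeology_map(split)
  expect_identical(nrow(map2), 2L)
  expect_setequal(map2$a_chrom, c("A9", "A10"))
  expect_identical(unique(map2$c_chrom), "C9")
})

test_that("short runs and large gaps are discarded; probes partition", {
  loci <- rbind(
    make_loci("A1", seq(1e5, 5e6, length.out = 20), "C1",
              seq(1e5, 5e6, length.out = 20)),
    ## 3 stray probes pairing elsewhere cannot form a block
    make_loci("A1", c(5.1e6, 5.2e6, 5.3e6), "C5", c(1e5, 2e5, 3e5)))
  map <- build_homoeology_map(loci, min_block_probes = 5)
  expect_identical(unique(map$c_chrom), "C1")
  ## a 3 Mb gap breaks a run under max_gap = 2 Mb
  gap <- make_loci("A3", c(seq(1e5, 1e6, length.out = 10),
                           seq(4e6, 5e6, length.out = 10)),
                   "C3", c(seq(1e5, 1e6, length.out = 10),
                           seq(4e6, 5e6, length.out = 10)))
  expect_identical(nrow(build_homoeology_map(gap, min_block_probes = 5)), 2L)
  ## partition: primary intervals of blocks on the same pair do not overlap
  ov <- build_homoeology_map(gap, min_block_probes = 5)
  expect_lt(ov$a_end[1L], ov$a_start[2L])
})

test_that("block construction equals the brute-force segmentation oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    ## 5 planted blocks across 3 primary chromosomes, ~2% shuffled probes
    pieces <- list()
    layout <- data.frame(
      pc = c("A1", "A1", "A2", "A3", "A3"),
      hc = c("C1", "C4", "C2", "C3", "C7"),
      inv = c(FALSE, TRUE, FALSE, FALSE, TRUE))
    offset <- c(A1 = 0, A2 = 0, A3 = 0)
    for (k in seq_len(nrow(layout))) {
      n <- sample(10:40, 1L)
      pc <- layout$pc[k]
      pp <- offset[[pc]] + cumsum(sample.int(5e5, n, replace = TRUE))
      offset[[pc]] <- max(pp) + 3e6  # separate planted blocks by > max_gap
      hp <- cumsum(sample.int(5e5, n, replace = TRUE)) + sample.int(1e6, 1L)
      if (layout$inv[k]) hp <- rev(hp)
      pieces[[k]] <- make_loci(pc, pp, layout$hc[k], hp)
    }
    loci <- do.call(rbind, pieces)
    shuffle <- sample(nrow(loci), max(1L, round(0.02 * nrow(loci))))
    loci$homoeo_pos[shuffle] <- sample.int(5e7, length(shuffle))
    loci$probe_id <- sprintf("p%04d", seq_len(nrow(loci)))
    got <- block_key(build_homoeology_map(loci, min_block_probes = 5,
                                          max_gap = 2e6))
    want <- oracle_homoeology_map(loci, min_block_probes = 5, max_gap = 2e6)
    expect_identical(got, want)
  }
})

test_that("interval projection maps through blocks, honouring inversion", {
  blk <- data.table::data.table(
    block_id = "b1", a_chrom = "A1", a_start = 1e6, a_end = 2e6,
    c_chrom = "C1", c_start = 4e6, c_end = 6e6, orientation = "same",
    n_probes = 10L)
  p <- project_interval(blk, "A1", 1.5e6, 2e6)
  expect_identical(p$chrom, "C1")
  expect_equal(p$start, 5e6)
  expect_equal(p$end, 6e6)
  blk$orientation <- "inverted"
  p2 <- project_interval(blk, "A1", 1e6, 1.5e6)
  expect_equal(c(p2$start, p2$end), c(5e6, 6e6))
  expect_null(project_interval(blk, "A1", 3e6, 4e6))
  expect_error(project_interval(blk, "A5", 1e6, 2e6), "not part")
})

test_that("hit tables round-trip through TSV and PSL readers", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#probe_id\tchromosome\tposition\tidentity",
               "p1\tA1\t100\t0.95", "p1\tC1\t200\t0.60"), tsv)
  hits <- read_probe_hits(tsv)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$subgenome, c("A", "C"))
  ## 21-column PSL: identity = matches / qSize, position = tStart + 1
  psl <- tempfile(fileext = ".psl")
  row <- c(57, 3, 0, 0, 0, 0, 0, 0, "+", "p9", 60, 0, 60, "C3", 1e6,
           4999, 5059, 1, 60, 0, 4999)
  writeLines(paste(row, collapse = "\t"), psl)
  ph <- read_probe_hits(psl)
  expect_identical(ph$probe_id, "p9")
  expect_identical(ph$position, 5000L)
  expect_equal(ph$identity, 0.95)
  ## BED export: one A-side and one C-side file sharing block ids
  loci <- make_loci("A1", seq(1e5, 1e7, length.out = 20), "C1",
                    seq(1e5, 1e7, length.out = 20))
  map <- build_homoeology_map(loci)
  out <- write_homoeology_bed(map, tempfile())
  a <- read.delim(out[1L], header = FALSE)
  c_ <- read.delim(out[2L], header = FALSE)
  expect_identical(a$V4, c_$V4)
  expect_identical(a$V2[1L], map$a_start - 1L)
})
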