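#' Classify a probe's subgenome specificity from its alignment hits
#'
#' Array probes are usable for subgenome-resolved genotyping only when their
#' flanking sequence matches one diploid progenitor genome well and the other
#' poorly.  Taking the best (maximum-identity) hit per subgenome, a probe is
#' `A_specific` when its best A-genome identity exceeds `high_thresh` while
#' the best C-genome identity does not (and symmetrically for `C_specific`);
#' `dual` when both exceed the threshold (such probes interrogate both
#' subgenomes with the same fluorophore pair, cannot be deconvolved, and are
#' excluded downstream); `unassigned` otherwise.  The comparison is strict
#' (`identity > high_thresh`): a hit at exactly the threshold does not count
#' as exceeding it.
#'
#' @param hits A data.frame of alignment hits for one probe with columns
#'   `subgenome` ("A"/"C") and `identity` (fraction in \[0, 1\]).  Zero rows
#'   are allowed.
#' @param high_thresh Identity threshold separating specific from
#'   non-specific matches (default 0.90).
#' @return One of `"A_specific"`, `"C_specific"`, `"dual"`, `"unassigned"`.
#' @export
classify_specificity <- function(hits, high_thresh = 0.90) {
  if (nrow(hits) == 0L) return("unassigned")
  if (any(hits$identity < 0 | hits$identity > 1 | is.na(hits$identity))) {
    stop("identity values must lie in [0, 1]")
  }
  best_a <- suppressWarnings(max(hits$identity[hits$subgenome == "A"]))
  best_c <- suppressWarnings(max(hits$identity[hits$subgenome == "C"]))
  a_hi <- is.finite(best_a) && best_a > high_thresh
  c_hi <- is.finite(best_c) && best_c > high_thresh
  if (a_hi && c_hi) "dual"
  else if (a_hi) "A_specific"
  else if (c_hi) "C_specific"
  else "unassigned"
}

#' Annotate probes with subgenome specificity and homoeologous locus
#'
#' For each probe the best hit per subgenome is selected (ties broken
#' deterministically by chromosome then position), specificity is classified
#' as in [classify_specificity()], and, for subgenome-specific probes, the
#' best hit in the *opposite* subgenome becomes the homoeologous locus when
#' its identity is at least `min_identity`.  Probes with such paired loci
#' anchor the A/C homoeology map used to match reciprocal gain/loss.
#'
#' @param hits Hit table with columns `probe_id`, `subgenome`, `chromosome`,
#'   `position`, `identity` (see [read_probe_hits()]).
#' @param high_thresh Specificity threshold, see [classify_specificity()].
#' @param min_identity Minimum opposite-genome identity required to assign a
#'   homoeologous locus (default 0.50).
#' @return A `data.table` (one row per probe): `probe_id`, `specificity`,
#'   `primary_chrom`, `primary_pos`, `homoeo_chrom`, `homoeo_pos`,
#'   `homoeo_identity`.  Locus columns are `NA` for `dual` and `unassigned`
#'   probes (dual probes are never used for genotyping).
#' @export
annotate_probes <- function(hits, high_thresh = 0.90, min_identity = 0.50) {
  hits <- data.table::as.data.table(hits)
  if (any(hits$identity < 0 | hits$identity > 1 | is.na(hits$identity))) {
    stop("identity values must lie in [0, 1]")
  }
  sg <- chromosome_subgenome(hits$chromosome)
  if (any(sg != hits$subgenome)) {
    stop("chromosome prefix does not match subgenome for some hits")
  }
  ## best hit per probe x subgenome; deterministic tie-break
  data.table::setorder(hits, probe_id, subgenome, -identity, chromosome,
                       position)
  best <- hits[, .SD[1L], by = .(probe_id, subgenome)]
  wide <- data.table::dcast(
    best, probe_id ~ subgenome,
    value.var = c("identity", "chromosome", "position")
  )
  for (col in c("identity_A", "identity_C", "chromosome_A", "chromosome_C",
                "position_A", "position_C")) {
    if (!col %in% names(wide)) wide[, (col) := NA]
  }
  a_hi <- !is.na(wide$identity_A) & wide$identity_A > high_thresh
  c_hi <- !is.na(wide$identity_C) & wide$identity_C > high_thresh
  spec <- data.table::fifelse(
    a_hi & c_hi, "dual",
    data.table::fifelse(a_hi, "A_specific",
    data.table::fifelse(c_hi, "C_specific", "unassigned")))
  out <- data.table::data.table(
    probe_id = wide$probe_id,
    specificity = spec,
    primary_chrom = NA_character_, primary_pos = NA_integer_,
    homoeo_chrom = NA_character_, homoeo_pos = NA_integer_,
    homoeo_identity = NA_real_
  )
  is_a <- spec == "A_specific"
  is_c <- spec == "C_specific"
  out$primary_chrom[is_a] <- wide$chromosome_A[is_a]
  out$primary_pos[is_a] <- as.integer(wide$position_A[is_a])
  out$primary_chrom[is_c] <- wide$chromosome_C[is_c]
  out$primary_pos[is_c] <- as.integer(wide$position_C[is_c])
  pair_a <- is_a & !is.na(wide$identity_C) & wide$identity_C >= min_identity
  pair_c <- is_c & !is.na(wide$identity_A) & wide$identity_A >= min_identity
  out$homoeo_chrom[pair_a] <- wide$chromosome_C[pair_a]
  out$homoeo_pos[pair_a] <- as.integer(wide$position_C[pair_a])
  out$homoeo_identity[pair_a] <- wide$identity_C[pair_a]
  out$homoeo_chrom[pair_c] <- wide$chromosome_A[pair_c]
  out$homoeo_pos[pair_c] <- as.integer(wide$position_A[pair_c])
  out$homoeo_identity[pair_c] <- wide$identity_A[pair_c]
  out[]
}

#' Build the homoeology block map from paired probe loci
#'
#' Probes carrying both a primary and a homoeologous locus are ordered by
#' primary position within each primary chromosome; maximal runs of
#' consecutive probes that (i) share the same (primary chromosome, partner
#' chromosome) pair, (ii) have monotone partner positions (either direction,
#' ties allowed) and (iii) are not interrupted by a gap larger than `max_gap`
#' on either side, are merged into syntenic blocks.  Runs shorter than
#' `min_block_probes` are discarded so that sparse spurious pairings cannot
#' form blocks.  Each retained probe belongs to exactly one block.
#'
#' @param loci Probe annotation as returned by [annotate_probes()]; only rows
#'   with both `primary_pos` and `homoeo_pos` present are used.
#' @param min_block_probes Minimum probes per block (default 5).
#' @param max_gap Maximum within-block gap in bp on either the primary or the
#'   partner side (default 2e6).
#' @return A `data.table` of blocks: `block_id`, `a_chrom`, `a_start`,
#'   `a_end`, `c_chrom`, `c_start`, `c_end`, `orientation` ("same" when
#'   partner position increases with primary position, "inverted" otherwise),
#'   `n_probes`.  The A interval always lies on an A chromosome regardless of
#'   which side the probes were primary on.
#' @export
build_homoeology_map <- function(loci, min_block_probes = 5, max_gap = 2e6) {
  loci <- data.table::as.data.table(loci)
  loci <- loci[!is.na(primary_pos) & !is.na(homoeo_pos)]
  if (nrow(loci) == 0L) return(empty_block_table())
  data.table::setorder(loci, primary_chrom, primary_pos, homoeo_pos)
  blocks <- list()
  for (pc in unique(loci$primary_chrom)) {
    sub <- loci[primary_chrom == pc]
    runs <- monotone_runs(sub$homoeo_chrom, sub$primary_pos, sub$homoeo_pos,
                          max_gap = max_gap)
    for (rn in runs) {
      if (length(rn) < min_block_probes) next
      blocks[[length(blocks) + 1L]] <- block_from_run(sub[rn])
    }
  }
  if (length(blocks) == 0L) return(empty_block_table())
  out <- data.table::rbindlist(blocks)
  data.table::setorder(out, a_chrom, a_start)
  out[, block_id := sprintf("blk_%03d", seq_len(.N))]
  data.table::setcolorder(out, "block_id")
  out[]
}

empty_block_table <- function() {
  data.table::data.table(
    block_id = character(), a_chrom = character(), a_start = integer(),
    a_end = integer(), c_chrom = character(), c_start = integer(),
    c_end = integer(), orientation = character(), n_probes = integer()
  )
}

## internal: greedy left-to-right segmentation of one primary chromosome into
## maximal runs sharing partner chromosome, with monotone (non-strict)
## partner positions and gaps <= max_gap on both sides.  Returns a list of
## index vectors.
monotone_runs <- function(partner_chrom, primary_pos, partner_pos, max_gap) {
  n <- length(partner_chrom)
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    dir <- 0L  # 0 undetermined, +1 increasing, -1 decreasing
    while (j < n) {
      k <- j + 1L
      if (partner_chrom[k] != partner_chrom[i]) break
      if (primary_pos[k] - primary_pos[j] > max_gap) break
      if (abs(partner_pos[k] - partner_pos[j]) > max_gap) break
      step <- sign(partner_pos[k] - partner_pos[j])
      if (dir == 0L) dir <- step
      else if (step != 0L && step != dir) break
      j <- k
    }
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

block_from_run <- function(sub) {
  prim_is_a <- chromosome_subgenome(sub$primary_chrom[1L]) == "A"
  if (prim_is_a) {
    a_chrom <- sub$primary_chrom[1L]; a_pos <- sub$primary_pos
    c_chrom <- sub$homoeo_chrom[1L]; c_pos <- sub$homoeo_pos
  } else {
    a_chrom <- sub$homoeo_chrom[1L]; a_pos <- sub$homoeo_pos
    c_chrom <- sub$primary_chrom[1L]; c_pos <- sub$primary_pos
  }
  ## orientation from the primary ordering: partner trend along primary
  trend <- sub$homoeo_pos[length(sub$homoeo_pos)] - sub$homoeo_pos[1L]
  data.table::data.table(
    a_chrom = a_chrom, a_start = min(a_pos), a_end = max(a_pos),
    c_chrom = c_chrom, c_start = min(c_pos), c_end = max(c_pos),
    orientation = if (trend < 0) "inverted" else "same",
    n_probes = nrow(sub)
  )
}

#' Project an interval through a homoeology block
#'
#' Positions within one side of a syntenic block are mapped linearly onto the
#' other side (reversed for inverted blocks).  Used to test whether a gain
#' run and a loss run on homoeologous chromosomes cover corresponding
#' territory.
#'
#' @param block One row of the block table from [build_homoeology_map()].
#' @param chrom,start,end Interval to project; `chrom` must equal the block's
#'   `a_chrom` or `c_chrom`.
#' @return A list `(chrom, start, end)` on the partner side, clipped to the
#'   block; `NULL` when the interval does not overlap the block.
#' @export
project_interval <- function(block, chrom, start, end) {
  if (chrom == block$a_chrom) {
    from <- c(block$a_start, block$a_end); to <- c(block$c_start, block$c_end)
    to_chrom <- block$c_chrom
  } else if (chrom == block$c_chrom) {
    from <- c(block$c_start, block$c_end); to <- c(block$a_start, block$a_end)
    to_chrom <- block$a_chrom
  } else {
    stop("interval chromosome ", chrom, " is not part of the block")
  }
  s <- max(start, from[1L]); e <- min(end, from[2L])
  if (s > e) return(NULL)
  span_from <- max(from[2L] - from[1L], 1L)
  f <- function(x) (x - from[1L]) / span_from
  if (identical(block$orientation, "inverted")) {
    p1 <- to[2L] - f(s) * (to[2L] - to[1L])
    p2 <- to[2L] - f(e) * (to[2L] - to[1L])
  } else {
    p1 <- to[1L] + f(s) * (to[2L] - to[1L])
    p2 <- to[1L] + f(e) * (to[2L] - to[1L])
  }
  list(chrom = to_chrom, start = round(min(p1, p2)), end = round(max(p1, p2)))
}

#' Read probe-to-genome alignment hits
#'
#' Two formats are supported: the simplified tab format with columns
#' `probe_id`, `chromosome`, `position`, `identity` (subgenome inferred from
#' the chromosome prefix; an explicit `subgenome` column is honoured when
#' present), and standard 21-column BLAT PSL (no header; identity computed as
#' matches / query size, position taken as the target start + 1, 1-based).
#'
#' @param file Path to the hit table.
#' @param format `"tsv"` or `"psl"`; default guesses from the file extension.
#' @return A `data.table` with columns `probe_id`, `subgenome`, `chromosome`,
#'   `position`, `identity`.
#' @export
read_probe_hits <- function(file, format = c("auto", "tsv", "psl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.psl$", file, ignore.case = TRUE)) "psl" else "tsv"
  }
  if (format == "psl") {
    psl <- data.table::fread(file, header = FALSE, sep = "\t",
                             skip = psl_skip(file))
    if (ncol(psl) < 17L) stop("not a 21-column PSL file: ", file)
    dt <- data.table::data.table(
      probe_id = as.character(psl[[10L]]),
      chromosome = as.character(psl[[14L]]),
      position = as.integer(psl[[16L]]) + 1L,
      identity = psl[[1L]] / pmax(psl[[11L]], 1L)
    )
  } else {
    dt <- read_tsv_commented(file)
    need <- c("probe_id", "chromosome", "position", "identity")
    if (!all(need %in% names(dt))) {
      stop("hit table must have columns: ", paste(need, collapse = ", "))
    }
  }
  if (!"subgenome" %in% names(dt)) {
    dt[, subgenome := chromosome_subgenome(chromosome)]
  }
  dt[, .(probe_id = as.character(probe_id), subgenome,
         chromosome = as.character(chromosome),
         position = as.integer(position), identity = as.numeric(identity))]
}

## PSL files may carry a 5-line header ("psLayout ...")
psl_skip <- function(file) {
  first <- readLines(file, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, "psLayout")) 5L else 0L
}

#' Write the homoeology map and probe annotation
#'
#' The block map is written as two BED6 files (A side and C side) sharing
#' `block_id` in the name column, plus the annotation table as TSV with a
#' `#`-prefixed header.
#'
#' @param blocks Block table from [build_homoeology_map()].
#' @param prefix Output path prefix; files `<prefix>_A.bed`,
#'   `<prefix>_C.bed` are created.
#' @return Invisibly, the written file paths.
#' @export
write_homoeology_bed <- function(blocks, prefix) {
  bed <- function(chrom, s, e, id, strand) {
    data.table::data.table(chrom = chrom, start = s - 1L, end = e,
                           name = id, score = 0L, strand = strand)
  }
  strand <- ifelse(blocks$orientation == "inverted", "-", "+")
  fa <- paste0(prefix, "_A.bed"); fc <- paste0(prefix, "_C.bed")
  utils::write.table(bed(blocks$a_chrom, blocks$a_start, blocks$a_end,
                         blocks$block_id, "+"),
                     fa, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(bed(blocks$c_chrom, blocks$c_start, blocks$c_end,
                         blocks$block_id, strand),
                     fc, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(fa, fc))
}

#' @rdname write_homoeology_bed
#' @param annotation Probe annotation from [annotate_probes()].
#' @param file Output TSV path.
#' @export
write_probe_annotation <- function(annotation, file) {
  write_tsv_commented(data.table::as.data.table(annotation), file)
}
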