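# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately avoid the incremental bookkeeping of the production
# code: everything is re-derived from first principles per candidate.

# Run-finder oracle: a run of class `cls` over [i, j] is valid when both ends
# carry `cls`, the interior carries only `cls` or "unknown", the interior
# unknown count is at most `gap_tolerance`, and at least `min_run` loci carry
# `cls`.  Runs are reported leftmost-greedy: from the first `cls` locus not
# yet consumed, take the largest valid j, then continue after j.
oracle_find_runs <- function(dosage, position, min_run = 3L,
                             gap_tolerance = 1L) {
  classes <- c("gain_of_parent1_allele", "gain_of_parent2_allele",
               "loss_of_parent1_allele", "loss_of_parent2_allele")
  out <- list()
  n <- length(dosage)
  valid <- function(i, j, cls) {
    if (dosage[i] != cls || dosage[j] != cls) return(FALSE)
    seg <- dosage[i:j]
    if (!all(seg %in% c(cls, "unknown"))) return(FALSE)
    sum(seg == "unknown") <= gap_tolerance
  }
  for (cls in classes) {
    i <- 1L
    while (i <= n) {
      if (dosage[i] != cls) { i <- i + 1L; next }
      j_best <- i
      for (j in i:n) if (valid(i, j, cls)) j_best <- j
      seg <- i:j_best
      sup <- seg[dosage[seg] == cls]
      if (length(sup) >= min_run) {
        out[[length(out) + 1L]] <- data.frame(
          direction = if (startsWith(cls, "gain")) "gain" else "loss",
          parent_of_origin = if (grepl("parent1", cls)) "parent1" else
            "parent2",
          start = position[sup[1L]], end = position[sup[length(sup)]],
          n_support = length(sup), stringsAsFactors = FALSE)
      }
      i <- j_best + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(direction = character(),
                      parent_of_origin = character(), start = numeric(),
                      end = numeric(), n_support = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$direction, res$parent_of_origin), , drop = FALSE]
}

# normalise a run table (either implementation) for comparison
run_key <- function(runs) {
  runs <- as.data.frame(runs)
  if (nrow(runs) == 0L) return(character())
  sort(paste(runs$direction, runs$parent_of_origin, runs$start, runs$end,
             runs$n_support, sep = "|"))
}

# Homoeology-map oracle: quadratic validity check over every candidate run,
# leftmost-greedy maximal segmentation per primary chromosome.
oracle_homoeology_map <- function(loci, min_block_probes = 5,
                                  max_gap = 2e6) {
  loci <- as.data.frame(loci)
  loci <- loci[!is.na(loci$primary_pos) & !is.na(loci$homoeo_pos), ]
  if (nrow(loci) == 0L) return(character())
  loci <- loci[order(loci$primary_chrom, loci$primary_pos,
                     loci$homoeo_pos), ]
  keys <- character()
  for (pc in unique(loci$primary_chrom)) {
    sub <- loci[loci$primary_chrom == pc, ]
    n <- nrow(sub)
    valid <- function(i, j) {
      if (length(unique(sub$homoeo_chrom[i:j])) != 1L) return(FALSE)
      if (j > i) {
        dp <- diff(sub$primary_pos[i:j])
        dh <- diff(sub$homoeo_pos[i:j])
        if (any(dp > max_gap) || any(abs(dh) > max_gap)) return(FALSE)
        s <- sign(dh); s <- s[s != 0]
        if (length(s) && length(unique(s)) > 1L) return(FALSE)
      }
      TRUE
    }
    i <- 1L
    while (i <= n) {
      j_best <- i
      for (j in i:n) if (valid(i, j)) j_best <- j
      if (j_best - i + 1L >= min_block_probes) {
        ix <- i:j_best
        prim_a <- substr(pc, 1L, 1L) == "A"
        a_chrom <- if (prim_a) pc else sub$homoeo_chrom[i]
        c_chrom <- if (prim_a) sub$homoeo_chrom[i] else pc
        a_pos <- if (prim_a) sub$primary_pos[ix] else sub$homoeo_pos[ix]
        c_pos <- if (prim_a) sub$homoeo_pos[ix] else sub$primary_pos[ix]
        keys <- c(keys, paste(a_chrom, min(a_pos), max(a_pos), c_chrom,
                              min(c_pos), max(c_pos), length(ix),
                              sep = "|"))
      }
      i <- j_best + 1L
    }
  }
  sort(keys)
}

block_key <- function(blocks) {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) == 0L) return(character())
  sort(paste(blocks$a_chrom, blocks$a_start, blocks$a_end, blocks$c_chrom,
             blocks$c_start, blocks$c_end, blocks$n_probes, sep = "|"))
}

# nearest flanking balanced marker by linear scan (breakpoint oracle)
oracle_breakpoint <- function(start, end, positions, ok, chrom_length) {
  left <- 1
  for (p in positions) if (ok[match(p, positions)] && p < start) left <- p
  right <- chrom_length
  for (p in rev(positions)) {
    if (ok[match(p, positions)] && p > end) right <- p
  }
  list(left = c(left, start), right = c(end, right))
}

# small intensity-record builder for genotyping tests
make_records <- function(theta, r = 1, individual = "X") {
  data.frame(individual_id = individual, theta = theta, r = r,
             stringsAsFactors = FALSE)
}

# long-format generating states of a simulated population's progeny
truth_states <- function(pop) {
  gm <- pop$truth_genotypes
  data.table::data.table(
    probe_id = rep(rownames(gm), ncol(gm)),
    individual_id = rep(colnames(gm), each = nrow(gm)),
    truth_state = as.vector(gm))
}

# end-to-end pipeline on a simulated population (shared by several tests)
run_pipeline <- function(pop) {
  gt <- call_genotypes(pop$intensities, pop$parents[1L], pop$parents[2L])
  detect_events(gt$calls, gt$markers, pop$marker_map$probes,
                pop$marker_map$blocks, pop$marker_map$chrom_models)
}
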