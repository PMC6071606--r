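#' Genotyping configuration
#'
#' Tuning parameters for the parental-anchored genotype caller.  All theta
#' quantities are in theta units (the two-channel fluorescence angle,
#' 0 = pure A allele, 1 = pure B allele).
#'
#' @param theta_aa_max Maximum theta for a parent to be classed AA
#'   (default 0.15, the optimal-separation bound for single-copy markers).
#' @param theta_bb_min Minimum theta for a parent to be classed BB
#'   (default 0.85).
#' @param r_amplification_floor A parent whose median R falls below this
#'   fraction of the marker's median R is treated as a null (non-amplifying)
#'   allele (default 0.25).
#' @param no_call_distance Distance-to-centre radius beyond which a progeny
#'   record is not called (default 0.08 theta units).  This replaces the
#'   proprietary GenCall score with a transparent geometric rule.
#' @param hemizygote_r_fraction Expected R of single-allele (A0/B0) states
#'   relative to full amplification; used only by the simulator and the
#'   optional hemizygote check (default 0.75).
#' @param min_cluster_n Minimum progeny falling between two anchored centres
#'   before the intermediate (AAB/ABB) centre is re-estimated as their median
#'   rather than the arithmetic midpoint (default 3).
#' @return A list of class `genotyping_config`.
#' @export
genotyping_config <- function(theta_aa_max = 0.15, theta_bb_min = 0.85,
                              r_amplification_floor = 0.25,
                              no_call_distance = 0.08,
                              hemizygote_r_fraction = 0.75,
                              min_cluster_n = 3L) {
  stopifnot(theta_aa_max > 0, theta_aa_max < 0.5,
            theta_bb_min > 0.5, theta_bb_min < 1,
            no_call_distance > 0, r_amplification_floor >= 0)
  structure(list(theta_aa_max = theta_aa_max, theta_bb_min = theta_bb_min,
                 r_amplification_floor = r_amplification_floor,
                 no_call_distance = no_call_distance,
                 hemizygote_r_fraction = hemizygote_r_fraction,
                 min_cluster_n = as.integer(min_cluster_n)),
            class = "genotyping_config")
}

GENOTYPES <- c("AA", "AB", "BB", "A0", "B0", "AAB", "ABB", "NC")

#' Classify one marker's cluster pattern from parental anchors
#'
#' Replicated parent wells are averaged by median.  A marker is
#' `monomorphic` when both parents fall in the same homozygous cluster,
#' `null_parent` when exactly one parent fails to amplify (median R below
#' `r_amplification_floor` times the marker median R), `failed` when the
#' parents cannot be anchored (all-zero intensities, heterozygous or
#' mid-range parents, both null), `standard_3_cluster` when the parents are
#' opposite homozygotes and every progeny record lies within
#' `no_call_distance` of the AA/AB/BB centres, and `multi_cluster` when
#' additional progeny groupings sit between AB and a parent (the signature of
#' allele gain/loss: AAB/ABB and A0/B0 states).
#'
#' Cluster centres: AA and BB are the parental medians, AB their midpoint;
#' AAB and ABB default to the arithmetic midpoints of (AA, AB) and (AB, BB)
#' and are re-estimated as the group median when at least `min_cluster_n`
#' progeny fall nearest to them.
#'
#' @param parent1_records,parent2_records,progeny_records data.frames with
#'   columns `theta` and `r` (and optionally `individual_id`).
#' @param config A [genotyping_config()].
#' @return A list of class `marker_classification`: `pattern`,
#'   `parent1_genotype`, `parent2_genotype` (AA/BB/null/NC), `centers`
#'   (named numeric, theta centre per genotype state), `aa_parent`
#'   (1 or 2: which parent anchors the AA cluster; NA when not polymorphic).
#' @export
classify_marker <- function(parent1_records, parent2_records,
                            progeny_records, config = genotyping_config()) {
  t1 <- stats::median(parent1_records$theta)
  t2 <- stats::median(parent2_records$theta)
  r1 <- stats::median(parent1_records$r)
  r2 <- stats::median(parent2_records$r)
  med_r <- stats::median(c(parent1_records$r, parent2_records$r,
                           progeny_records$r))
  out <- list(pattern = "failed",
              parent1_genotype = "NC", parent2_genotype = "NC",
              centers = NULL, aa_parent = NA_integer_)
  class(out) <- "marker_classification"
  if (med_r <= 0) return(out)
  null1 <- r1 < config$r_amplification_floor * med_r
  null2 <- r2 < config$r_amplification_floor * med_r
  geno <- function(th) {
    if (th <= config$theta_aa_max) "AA"
    else if (th >= config$theta_bb_min) "BB" else "NC"
  }
  g1 <- if (null1) "null" else geno(t1)
  g2 <- if (null2) "null" else geno(t2)
  out$parent1_genotype <- g1
  out$parent2_genotype <- g2
  if (null1 && null2) return(out)
  if (xor(null1, null2)) {
    amp <- if (null1) g2 else g1
    if (amp == "NC") return(out)
    out$pattern <- "null_parent"
    out$centers <- c(stats::setNames(if (null1) t2 else t1, amp))
    return(out)
  }
  if (g1 == "NC" || g2 == "NC") return(out)
  if (g1 == g2) { out$pattern <- "monomorphic"; return(out) }
  out$aa_parent <- if (g1 == "AA") 1L else 2L
  aa <- if (g1 == "AA") t1 else t2
  bb <- if (g1 == "BB") t1 else t2
  ab <- (aa + bb) / 2
  centers <- c(AA = aa, AAB = (aa + ab) / 2, AB = ab,
               ABB = (ab + bb) / 2, BB = bb)
  ## re-estimate intermediate centres from the progeny when supported
  th <- progeny_records$theta
  if (length(th) == 0L) {
    out$centers <- centers
    out$pattern <- "standard_3_cluster"
    return(out)
  }
  nearest <- apply(abs(outer(th, centers, "-")), 1L, which.min)
  for (st in names(centers)) {
    idx <- which(nearest == match(st, names(centers)))
    keep <- idx[abs(th[idx] - centers[[st]]) <= config$no_call_distance]
    if (length(keep) >= config$min_cluster_n) {
      centers[[st]] <- stats::median(th[keep])
    }
  }
  out$centers <- centers
  d <- abs(outer(th, centers, "-"))
  nearest <- apply(d, 1L, which.min)
  dist <- d[cbind(seq_along(th), nearest)]
  called <- dist <= config$no_call_distance
  out$pattern <- if (any(called & names(centers)[nearest] != "AB")) {
    "multi_cluster"
  } else {
    "standard_3_cluster"
  }
  out
}

#' Call one progeny genotype by nearest anchored centre
#'
#' Assignment is over the five theta centres AA/AAB/AB/ABB/BB of the marker
#' classification.  A progeny record landing in a parental homozygous cluster
#' at a polymorphic marker carries a single inherited allele and is called
#' `A0` (or `B0`), never AA/BB.  Records farther than the no-call radius from
#' every centre are `NC`.  At `null_parent` markers every progeny carries
#' only the amplifying parent's allele and is called `A0`/`B0` accordingly.
#'
#' @param record One-row data.frame with `theta` (and `r`).
#' @param classification A [classify_marker()] result with pattern
#'   `standard_3_cluster`, `multi_cluster` or `null_parent`.
#' @param config A [genotyping_config()].
#' @return A list: `genotype` (one of AA/AB/BB/A0/B0/AAB/ABB/NC) and
#'   `confidence` (theta distance to the assigned centre).
#' @export
call_progeny_genotype <- function(record, classification,
                                  config = genotyping_config()) {
  pat <- classification$pattern
  if (pat %in% c("failed", "monomorphic")) {
    stop("marker is not callable for progeny (pattern ", pat, ")")
  }
  th <- record$theta
  if (pat == "null_parent") {
    amp <- names(classification$centers)[1L]
    d <- abs(th - classification$centers[[1L]])
    g <- if (d <= config$no_call_distance) {
      if (amp == "AA") "A0" else "B0"
    } else "NC"
    return(list(genotype = g, confidence = d))
  }
  centers <- classification$centers
  d <- abs(th - centers)
  i <- which.min(d)
  if (d[[i]] > config$no_call_distance) {
    return(list(genotype = "NC", confidence = d[[i]]))
  }
  g <- names(centers)[i]
  if (g == "AA") g <- "A0"
  if (g == "BB") g <- "B0"
  list(genotype = g, confidence = d[[i]])
}

#' Vectorised population genotyping
#'
#' Classifies every marker from the two parents' records and calls all
#' progeny records by nearest anchored centre, as in [classify_marker()] and
#' [call_progeny_genotype()] but computed table-wise.
#'
#' @param intensities Long-format table with columns `individual_id`,
#'   `probe_id`, `theta`, `r`.
#' @param parent1_id,parent2_id Individual ids of the two parents.
#' @param config A [genotyping_config()].
#' @return A list with `markers` (per-probe classification: `probe_id`,
#'   `pattern`, `parent1_genotype`, `parent2_genotype`, `aa_parent`, centre
#'   columns `c_aa`, `c_aab`, `c_ab`, `c_abb`, `c_bb`) and `calls`
#'   (per progeny record: `individual_id`, `probe_id`, `genotype`,
#'   `confidence`).
#' @export
call_genotypes <- function(intensities, parent1_id, parent2_id,
                           config = genotyping_config()) {
  dt <- data.table::as.data.table(intensities)
  stopifnot(all(c("individual_id", "probe_id", "theta", "r") %in% names(dt)))
  if (any(dt$theta < 0 | dt$theta > 1, na.rm = TRUE) ||
      any(dt$r < 0, na.rm = TRUE)) {
    stop("theta must lie in [0, 1] and r must be >= 0")
  }
  p1 <- dt[individual_id == parent1_id,
           .(t1 = stats::median(theta), r1 = stats::median(r)), by = probe_id]
  p2 <- dt[individual_id == parent2_id,
           .(t2 = stats::median(theta), r2 = stats::median(r)), by = probe_id]
  medr <- dt[, .(med_r = stats::median(r)), by = probe_id]
  mk <- Reduce(function(x, y) merge(x, y, by = "probe_id", all = TRUE),
               list(p1, p2, medr))
  cfg <- config
  mk[, `:=`(
    null1 = !is.na(r1) & r1 < cfg$r_amplification_floor * med_r,
    null2 = !is.na(r2) & r2 < cfg$r_amplification_floor * med_r
  )]
  pg <- function(th) data.table::fifelse(
    th <= cfg$theta_aa_max, "AA",
    data.table::fifelse(th >= cfg$theta_bb_min, "BB", "NC"))
  mk[, `:=`(parent1_genotype = data.table::fifelse(null1, "null", pg(t1)),
            parent2_genotype = data.table::fifelse(null2, "null", pg(t2)))]
  mk[is.na(parent1_genotype), parent1_genotype := "NC"]
  mk[is.na(parent2_genotype), parent2_genotype := "NC"]
  mk[, pattern := "failed"]
  mk[xor(null1, null2) &
       data.table::fifelse(null1, parent2_genotype, parent1_genotype)
       %in% c("AA", "BB"),
     pattern := "null_parent"]
  mk[!null1 & !null2 & parent1_genotype %in% c("AA", "BB") &
       parent1_genotype == parent2_genotype, pattern := "monomorphic"]
  poly <- !mk$null1 & !mk$null2 &
    ((mk$parent1_genotype == "AA" & mk$parent2_genotype == "BB") |
     (mk$parent1_genotype == "BB" & mk$parent2_genotype == "AA"))
  mk[, aa_parent := NA_integer_]
  mk[poly, aa_parent := data.table::fifelse(parent1_genotype == "AA", 1L, 2L)]
  mk[, `:=`(c_aa = NA_real_, c_ab = NA_real_, c_bb = NA_real_,
            c_aab = NA_real_, c_abb = NA_real_)]
  mk[poly, `:=`(c_aa = data.table::fifelse(aa_parent == 1L, t1, t2),
                c_bb = data.table::fifelse(aa_parent == 1L, t2, t1))]
  mk[poly, c_ab := (c_aa + c_bb) / 2]
  mk[poly, `:=`(c_aab = (c_aa + c_ab) / 2, c_abb = (c_ab + c_bb) / 2)]
  ## null_parent centre: the amplifying parent's theta
  mk[pattern == "null_parent",
     c_np := data.table::fifelse(null1, t2, t1)]
  mk[pattern == "null_parent",
     np_geno := data.table::fifelse(null1, parent2_genotype,
                                    parent1_genotype)]

  prog <- dt[!individual_id %in% c(parent1_id, parent2_id)]
  calls <- merge(prog, mk, by = "probe_id")
  ## polymorphic markers: nearest of the five centres
  pcalls <- calls[!is.na(aa_parent)]
  if (nrow(pcalls)) {
    cc <- c("c_aa", "c_aab", "c_ab", "c_abb", "c_bb")
    dmat <- abs(as.matrix(pcalls[, ..cc]) - pcalls$theta)
    ## re-estimate every cluster centre as the group median of its
    ## provisional members (>= min_cluster_n within the no-call radius);
    ## single noisy parent wells are poor anchors for dense clusters
    prov <- max.col(-dmat, ties.method = "first")
    states <- c("AA", "AAB", "AB", "ABB", "BB")
    pcalls[, prov_state := states[prov]]
    pcalls[, prov_dist := dmat[cbind(.I, prov)]]
    upd <- pcalls[prov_dist <= cfg$no_call_distance,
                  .(n = .N, ctr = stats::median(theta)),
                  by = .(probe_id, prov_state)]
    upd <- upd[n >= cfg$min_cluster_n]
    if (nrow(upd)) {
      w <- data.table::dcast(upd, probe_id ~ prov_state, value.var = "ctr")
      for (k in seq_along(states)) {
        st <- states[k]
        if (!st %in% names(w)) next
        sel <- w[!is.na(w[[st]]), c("probe_id", st), with = FALSE]
        data.table::setnames(sel, st, "new_ctr")
        pcalls[sel, (cc[k]) := i.new_ctr, on = "probe_id"]
      }
      dmat <- abs(as.matrix(pcalls[, ..cc]) - pcalls$theta)
      ## push refreshed centres back into the marker table
      upd_w <- unique(pcalls[, c("probe_id", cc), with = FALSE])
      for (col in cc) {
        mk[upd_w, (col) := get(paste0("i.", col)), on = "probe_id"]
      }
    }
    best <- max.col(-dmat, ties.method = "first")
    state <- c("A0", "AAB", "AB", "ABB", "B0")[best]
    dist <- dmat[cbind(seq_len(nrow(dmat)), best)]
    pcalls[, `:=`(genotype = data.table::fifelse(
      dist > cfg$no_call_distance, "NC", state), confidence = dist)]
  }
  ## null-parent markers: single cluster with the amplifying parent
  ncalls <- calls[pattern == "null_parent"]
  if (nrow(ncalls)) {
    d <- abs(ncalls$theta - ncalls$c_np)
    g <- ifelse(ncalls$np_geno == "AA", "A0", "B0")
    ncalls[, `:=`(genotype = data.table::fifelse(
      d > cfg$no_call_distance, "NC", g), confidence = d)]
  }
  keep <- c("individual_id", "probe_id", "genotype", "confidence")
  call_tab <- data.table::rbindlist(list(
    if (nrow(pcalls)) pcalls[, ..keep],
    if (nrow(ncalls)) ncalls[, ..keep]
  ))
  ## marker pattern: polymorphic markers split standard vs multi-cluster
  if (nrow(pcalls)) {
    ab_only <- pcalls[, .(multi = any(genotype %in%
                                        c("A0", "B0", "AAB", "ABB"))),
                      by = probe_id]
    mk[ab_only, pattern := data.table::fifelse(
      i.multi, "multi_cluster", "standard_3_cluster"), on = "probe_id"]
  }
  mk[!is.na(aa_parent) & pattern == "failed", pattern := "standard_3_cluster"]
  marker_cols <- c("probe_id", "pattern", "parent1_genotype",
                   "parent2_genotype", "aa_parent",
                   "c_aa", "c_aab", "c_ab", "c_abb", "c_bb")
  list(markers = mk[, ..marker_cols], calls = call_tab)
}

#' Derive allele dosage from a genotype call
#'
#' At a polymorphic marker in a testcross F1 each parent contributes one
#' allele, so AB is the balanced expectation.  A single-allele call (A0/B0)
#' means the other parent's allele was lost in its meiosis; a three-dose call
#' (AAB/ABB) means one parent's allele arrived in two copies.
#'
#' @param genotype Character vector of calls (AA/AB/BB/A0/B0/AAB/ABB/NC).
#' @param aa_parent Integer vector: which parent (1 or 2) carries the
#'   low-theta A allele at each marker.
#' @return Character vector over `balanced`, `loss_of_parent1_allele`,
#'   `loss_of_parent2_allele`, `gain_of_parent1_allele`,
#'   `gain_of_parent2_allele`, `unknown`.
#' @export
derive_dosage <- function(genotype, aa_parent) {
  stopifnot(length(aa_parent) == length(genotype) || length(aa_parent) == 1L)
  if (length(aa_parent) == 1L) aa_parent <- rep(aa_parent, length(genotype))
  a_par <- as.integer(aa_parent)          # parent carrying the A allele
  b_par <- 3L - a_par                     # parent carrying the B allele
  out <- rep("unknown", length(genotype))
  out[genotype == "AB"] <- "balanced"
  sel <- genotype == "A0"                 # B allele missing
  out[sel] <- paste0("loss_of_parent", b_par[sel], "_allele")
  sel <- genotype == "B0"                 # A allele missing
  out[sel] <- paste0("loss_of_parent", a_par[sel], "_allele")
  sel <- genotype == "AAB"                # A allele doubled
  out[sel] <- paste0("gain_of_parent", a_par[sel], "_allele")
  sel <- genotype == "ABB"                # B allele doubled
  out[sel] <- paste0("gain_of_parent", b_par[sel], "_allele")
  out[is.na(genotype)] <- "unknown"
  out
}

#' Read and write intensity and genotype tables
#'
#' `read_intensity_tsv()` reads a long-format GenomeStudio-final-report-like
#' export.  Column names are normalised: `Sample ID`/`sample_id` to
#' `individual_id`, `SNP Name`/`snp_name` to `probe_id`, `Theta` to `theta`,
#' `R` to `r`.  `write_genotype_matrix()` writes a markers x individuals
#' matrix of 8-state codes.
#'
#' @param file Path to the TSV.
#' @return `read_intensity_tsv()`: a `data.table` with `individual_id`,
#'   `probe_id`, `theta`, `r`.
#' @export
read_intensity_tsv <- function(file) {
  dt <- read_tsv_commented(file)
  nm <- tolower(gsub("[ .]", "_", names(dt)))
  nm[nm %in% c("sample_id", "sample")] <- "individual_id"
  nm[nm %in% c("snp_name", "snp", "marker", "marker_id")] <- "probe_id"
  data.table::setnames(dt, nm)
  need <- c("individual_id", "probe_id", "theta", "r")
  if (!all(need %in% nm)) {
    stop("intensity table must provide columns: ",
         paste(need, collapse = ", "))
  }
  dt[, .(individual_id = as.character(individual_id),
         probe_id = as.character(probe_id),
         theta = as.numeric(theta), r = as.numeric(r))]
}

#' @rdname read_intensity_tsv
#' @param calls Call table from [call_genotypes()].
#' @export
write_genotype_matrix <- function(calls, file) {
  dt <- data.table::as.data.table(calls)
  wide <- data.table::dcast(dt, probe_id ~ individual_id,
                            value.var = "genotype", fill = "NC")
  write_tsv_commented(wide, file)
}
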