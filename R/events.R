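#' Find aberrant dosage runs along one chromosome
#'
#' Scans a position-ordered vector of dosage calls for one individual on one
#' chromosome and returns every maximal run of at least `min_run` loci with
#' the same aberrant dosage (same direction *and* same parent of origin).
#' Up to `gap_tolerance` interior `unknown` calls are bridged per run;
#' any conflicting call — `balanced` or a different aberrant class — always
#' breaks a run.  Three or more consecutive aberrant loci are the minimum
#' evidence for an affected region; leading/trailing unknowns never extend a
#' run.
#'
#' @param dosage Character vector over `balanced`,
#'   `loss_of_parent1_allele`, `loss_of_parent2_allele`,
#'   `gain_of_parent1_allele`, `gain_of_parent2_allele`, `unknown`, ordered
#'   by position.
#' @param position Numeric vector of bp positions, strictly increasing.
#' @param min_run Minimum supporting loci per run (default 3).
#' @param gap_tolerance Maximum interior `unknown` calls bridged per run
#'   (default 1).
#' @return A `data.table` with one row per run: `direction` ("gain"/"loss"),
#'   `parent_of_origin` ("parent1"/"parent2"), `start`, `end` (outermost
#'   affected positions), `first_index`, `last_index` (indices into the
#'   input), `n_support` (aberrant loci in the run, bridged unknowns not
#'   counted).
#' @export
find_aberrant_runs <- function(dosage, position, min_run = 3L,
                               gap_tolerance = 1L) {
  n <- length(dosage)
  position <- as.numeric(position)
  stopifnot(length(position) == n)
  if (n > 1L && any(diff(position) < 0)) {
    stop("positions must be sorted in increasing order")
  }
  out <- list()
  for (cls in c("gain_of_parent1_allele", "gain_of_parent2_allele",
                "loss_of_parent1_allele", "loss_of_parent2_allele")) {
    idx <- run_scan(dosage == cls, dosage == "unknown",
                    min_run = min_run, gap_tolerance = gap_tolerance)
    for (rn in idx) {
      sup <- rn[dosage[rn] == cls]
      out[[length(out) + 1L]] <- data.table::data.table(
        direction = if (startsWith(cls, "gain")) "gain" else "loss",
        parent_of_origin = if (grepl("parent1", cls)) "parent1" else
          "parent2",
        start = position[sup[1L]], end = position[sup[length(sup)]],
        first_index = sup[1L], last_index = sup[length(sup)],
        n_support = length(sup)
      )
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(
      direction = character(), parent_of_origin = character(),
      start = numeric(), end = numeric(), first_index = integer(),
      last_index = integer(), n_support = integer()))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, start)
  res[]
}

## internal: maximal runs of `hit` positions bridged by at most
## `gap_tolerance` interior `bridge` positions; anything else breaks.
## Returns list of index ranges (first hit .. last hit).
run_scan <- function(hit, bridge, min_run, gap_tolerance) {
  n <- length(hit)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!hit[i]) { i <- i + 1L; next }
    j <- i
    used_gap <- 0L
    k <- j + 1L
    while (k <= n) {
      if (hit[k]) { j <- k; k <- k + 1L; next }
      if (bridge[k]) {
        ## count consecutive bridgeable positions until next hit
        m <- k
        while (m <= n && bridge[m]) m <- m + 1L
        gap_len <- m - k
        if (m <= n && hit[m] && used_gap + gap_len <= gap_tolerance) {
          used_gap <- used_gap + gap_len
          j <- m; k <- m + 1L; next
        }
      }
      break
    }
    if (sum(hit[i:j]) >= min_run) runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

#' Collect aberrant runs for every individual and chromosome
#'
#' Convenience wrapper applying [find_aberrant_runs()] per individual and
#' chromosome over a dosage call table.
#'
#' @param dosage_calls Table with columns `individual_id`, `chromosome`,
#'   `position`, `dosage` (see [derive_dosage()]).
#' @param merge_nc Merge same-class runs separated only by unknown calls
#'   into one region (default TRUE).  Run *finding* stays conservative (at
#'   most `gap_tolerance` bridged unknowns); merging is region assembly on
#'   top of it and never crosses a balanced or conflicting call.
#' @inheritParams find_aberrant_runs
#' @return A `data.table` of runs with `individual_id` and `chromosome`
#'   columns added.
#' @export
find_runs_by_individual <- function(dosage_calls, min_run = 3L,
                                    gap_tolerance = 1L, merge_nc = TRUE) {
  dt <- data.table::as.data.table(dosage_calls)
  data.table::setorder(dt, individual_id, chromosome, position)
  runs <- dt[, {
    r <- find_aberrant_runs(dosage, position, min_run = min_run,
                            gap_tolerance = gap_tolerance)
    if (merge_nc && nrow(r) > 1L) r <- merge_runs_over_nc(r, dosage)
    r
  }, by = .(individual_id, chromosome)]
  runs
}

#' Reclassify whole-chromosome runs as aneuploidy
#'
#' Gain or loss of a whole chromosome shows as aberrant calls across
#' (nearly) all of its informative loci.  Runs of one individual on one
#' chromosome with the same direction and parent of origin are judged
#' jointly: when their combined support covers at least
#' `aneuploid_fraction` of the chromosome's informative loci the chromosome
#' is aneuploid, the runs are removed from homoeologous pairing, and a
#' single whole-chromosome event is emitted.  One individual may carry
#' several aneuploid chromosomes.
#'
#' @param runs Run table from [find_runs_by_individual()].
#' @param informative_counts Table with `chromosome` and `n_informative`:
#'   either per chromosome (informative polymorphic loci) or, when an
#'   `individual_id` column is present, the individual's scorable
#'   (non-missing, non-no-call) informative loci per chromosome — the
#'   latter keeps the coverage fraction honest when no-call rates vary.
#' @param aneuploid_fraction Coverage fraction above which a chromosome
#'   becomes aneuploid (default 0.95).
#' @return A list: `aneuploid` (one row per aneuploid chromosome with total
#'   `n_support`) and `segmental` (remaining runs).
#' @export
detect_aneuploidy <- function(runs, informative_counts,
                              aneuploid_fraction = 0.95) {
  runs <- data.table::as.data.table(runs)
  ic <- data.table::as.data.table(informative_counts)
  if (nrow(runs) == 0L) return(list(aneuploid = runs, segmental = runs))
  grp_cols <- intersect(c("individual_id", "chromosome", "direction",
                          "parent_of_origin"), names(runs))
  agg <- runs[, .(total_support = sum(n_support), start = min(start),
                  end = max(end), n_support = sum(n_support)),
              by = grp_cols]
  by_cols <- intersect(c("individual_id", "chromosome"), names(ic))
  agg <- merge(agg, ic, by = by_cols, all.x = TRUE)
  agg[, aneu := !is.na(n_informative) &
        total_support >= aneuploid_fraction * n_informative]
  aneu_groups <- agg[aneu == TRUE]
  seg <- merge(runs, agg[, c(grp_cols, "aneu"), with = FALSE],
               by = grp_cols)
  list(aneuploid = aneu_groups,
       segmental = seg[aneu == FALSE, names(runs), with = FALSE])
}

## internal: merge same-class runs on one chromosome separated by unknown
## calls and at most one isolated discordant call (region assembly above
## the conservative run finder; an isolated miscall must not split an
## assembled region, two or more consecutive discordant calls do)
merge_runs_over_nc <- function(runs, dosage, conflict_tolerance = 1L) {
  if (nrow(runs) <= 1L) return(runs)
  data.table::setorder(runs, direction, parent_of_origin, start)
  out <- list()
  cur <- runs[1L]
  for (i in 2L:nrow(runs)) {
    nxt <- runs[i]
    between <- if (nxt$first_index > cur$last_index + 1L) {
      dosage[(cur$last_index + 1L):(nxt$first_index - 1L)]
    } else character()
    if (nxt$direction == cur$direction &&
        nxt$parent_of_origin == cur$parent_of_origin &&
        sum(between != "unknown") <= conflict_tolerance) {
      cur$end <- nxt$end
      cur$last_index <- nxt$last_index
      cur$n_support <- cur$n_support + nxt$n_support
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- data.table::rbindlist(out)
  data.table::setorder(res, start)
  res
}

#' Match reciprocal gain/loss runs into homoeologous recombination events
#'
#' A loss run and a gain run of one individual form an HeR event when their
#' regions lie on homoeologous blocks whose projections overlap and both runs
#' share the parent of origin.  Each run participates in at most one HeR
#' (ties resolved by largest projected overlap, then map order — ambiguous
#' pairings are flagged).  Unpaired losses are deletions; unpaired gains are
#' duplications.
#'
#' @param runs Segmental run table for one individual (columns as returned
#'   by [find_runs_by_individual()]).
#' @param map Homoeology block table from [build_homoeology_map()].
#' @param min_support Minimum supporting loci on *each* side for an HeR call
#'   (default 3).
#' @return A `data.table` of events: `type` (`her`/`deletion`/`duplication`),
#'   `gain_chrom`, `gain_start`, `gain_end`, `n_support_gain`, `loss_chrom`,
#'   `loss_start`, `loss_end`, `n_support_loss`, `parent_of_origin`,
#'   `individual_id`, `flagged`.
#' @export
match_reciprocal <- function(runs, map, min_support = 3L) {
  runs <- data.table::as.data.table(runs)
  if (!"individual_id" %in% names(runs)) runs[, individual_id := NA_character_]
  gains <- which(runs$direction == "gain")
  losses <- which(runs$direction == "loss")
  cand <- list()
  for (g in gains) {
    for (l in losses) {
      if (!identical(runs$parent_of_origin[g],
                     runs$parent_of_origin[l])) next
      if (!identical(runs$individual_id[g], runs$individual_id[l])) next
      if (runs$n_support[g] < min_support ||
          runs$n_support[l] < min_support) next
      ov <- projected_overlap(map,
                              runs$chromosome[g], runs$start[g], runs$end[g],
                              runs$chromosome[l], runs$start[l], runs$end[l])
      if (ov > 0) {
        cand[[length(cand) + 1L]] <- data.table::data.table(
          g = g, l = l, overlap = ov)
      }
    }
  }
  paired_g <- integer(); paired_l <- integer(); flagged <- logical(0)
  if (length(cand)) {
    cand <- data.table::rbindlist(cand)
    data.table::setorder(cand, -overlap, g, l)
    amb_runs <- c(cand$g[duplicated(cand$g)], cand$l[duplicated(cand$l)])
    for (ii in seq_len(nrow(cand))) {
      g <- cand$g[ii]; l <- cand$l[ii]
      if (g %in% paired_g || l %in% paired_l) next
      paired_g <- c(paired_g, g); paired_l <- c(paired_l, l)
      flagged <- c(flagged, g %in% amb_runs || l %in% amb_runs)
    }
  }
  ev <- list()
  for (ii in seq_along(paired_g)) {
    g <- paired_g[ii]; l <- paired_l[ii]
    ev[[length(ev) + 1L]] <- data.table::data.table(
      type = "her",
      gain_chrom = runs$chromosome[g], gain_start = runs$start[g],
      gain_end = runs$end[g], n_support_gain = runs$n_support[g],
      loss_chrom = runs$chromosome[l], loss_start = runs$start[l],
      loss_end = runs$end[l], n_support_loss = runs$n_support[l],
      parent_of_origin = runs$parent_of_origin[g],
      individual_id = runs$individual_id[g],
      flagged = flagged[ii]
    )
  }
  for (g in setdiff(gains, paired_g)) {
    ev[[length(ev) + 1L]] <- data.table::data.table(
      type = "duplication",
      gain_chrom = runs$chromosome[g], gain_start = runs$start[g],
      gain_end = runs$end[g], n_support_gain = runs$n_support[g],
      loss_chrom = NA_character_, loss_start = NA_real_, loss_end = NA_real_,
      n_support_loss = NA_integer_,
      parent_of_origin = runs$parent_of_origin[g],
      individual_id = runs$individual_id[g], flagged = FALSE
    )
  }
  for (l in setdiff(losses, paired_l)) {
    ev[[length(ev) + 1L]] <- data.table::data.table(
      type = "deletion",
      gain_chrom = NA_character_, gain_start = NA_real_, gain_end = NA_real_,
      n_support_gain = NA_integer_,
      loss_chrom = runs$chromosome[l], loss_start = runs$start[l],
      loss_end = runs$end[l], n_support_loss = runs$n_support[l],
      parent_of_origin = runs$parent_of_origin[l],
      individual_id = runs$individual_id[l], flagged = FALSE
    )
  }
  if (length(ev) == 0L) return(empty_event_table())
  data.table::rbindlist(ev)
}

## internal: overlap (bp) between the projection of interval 1 through any
## shared homoeology block and interval 2
projected_overlap <- function(map, chrom1, s1, e1, chrom2, s2, e2) {
  best <- 0
  hit <- map[(a_chrom == chrom1 & c_chrom == chrom2) |
               (c_chrom == chrom1 & a_chrom == chrom2)]
  for (bi in seq_len(nrow(hit))) {
    blk <- hit[bi]
    proj <- project_interval(blk, chrom1, s1, e1)
    if (is.null(proj)) next
    ov <- min(proj$end, e2) - max(proj$start, s2) + 1
    if (ov > best) best <- ov
  }
  best
}

empty_event_table <- function() {
  data.table::data.table(
    type = character(), gain_chrom = character(), gain_start = numeric(),
    gain_end = numeric(), n_support_gain = integer(),
    loss_chrom = character(), loss_start = numeric(), loss_end = numeric(),
    n_support_loss = integer(), parent_of_origin = character(),
    individual_id = character(), flagged = logical()
  )
}

#' Classify event inheritance within a testcross population
#'
#' Two events are "the same" when they have the same type, direction,
#' chromosome(s) and parent of origin and their regions overlap reciprocally
#' by at least `overlap_fraction`.  An event seen in exactly one individual
#' arose in the sampled meiosis (`de_novo`); in more than one but not all
#' individuals it was heterozygous in a parent (`segregating`); in every
#' individual it is `fixed`.
#'
#' @param events Event table for one population.
#' @param population_size Number of testcross individuals genotyped.
#' @param overlap_fraction Reciprocal overlap threshold (default 0.5).
#' @return The event table with an `inheritance` column added.
#' @export
classify_inheritance <- function(events, population_size,
                                 overlap_fraction = 0.5) {
  events <- data.table::as.data.table(events)
  if (population_size < 2) {
    events[, inheritance := "unclassified"]
    return(events[])
  }
  n <- nrow(events)
  if (n == 0L) { events[, inheritance := character()] ; return(events[]) }
  same <- function(i, j) {
    if (events$type[i] != events$type[j]) return(FALSE)
    if (!identical(events$parent_of_origin[i],
                   events$parent_of_origin[j])) return(FALSE)
    for (side in c("gain", "loss")) {
      ci <- events[[paste0(side, "_chrom")]][i]
      cj <- events[[paste0(side, "_chrom")]][j]
      if (is.na(ci) != is.na(cj)) return(FALSE)
      if (is.na(ci)) next
      if (ci != cj) return(FALSE)
      ri <- c(events[[paste0(side, "_start")]][i],
              events[[paste0(side, "_end")]][i])
      rj <- c(events[[paste0(side, "_start")]][j],
              events[[paste0(side, "_end")]][j])
      if (!reciprocal_overlap_ok(ri, rj, overlap_fraction)) return(FALSE)
    }
    TRUE
  }
  ## union-find style grouping (event sets are small)
  grp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (grp[i] != grp[j] && same(i, j)) grp[grp == grp[j]] <- grp[i]
  }
  counts <- vapply(split(seq_len(n), grp), function(ix) {
    length(unique(events$individual_id[ix]))
  }, integer(1L))
  lab <- vapply(counts, function(k) {
    if (k == 1L) "de_novo"
    else if (k >= population_size) "fixed"
    else "segregating"
  }, character(1L))
  events[, inheritance := lab[as.character(grp)]]
  events[]
}

reciprocal_overlap_ok <- function(r1, r2, frac) {
  ov <- min(r1[2L], r2[2L]) - max(r1[1L], r2[1L]) + 1
  if (ov <= 0) return(FALSE)
  ov >= frac * (r1[2L] - r1[1L] + 1) && ov >= frac * (r2[2L] - r2[1L] + 1)
}

#' Breakpoint uncertainty intervals for an event edge
#'
#' Each edge of an affected region is localised between the outermost
#' affected probe and the nearest flanking informative probe carrying a
#' normal (balanced) call; when the run reaches the first or last probe the
#' interval is truncated at the chromosome end.
#'
#' @param start,end Outermost affected probe positions of the region.
#' @param positions Positions of informative probes on the chromosome
#'   (sorted).
#' @param ok Logical vector: which of `positions` carry a balanced call for
#'   this individual.
#' @param chrom_length Chromosome length in bp.
#' @return A list of two `(bp, bp)` vectors: left and right breakpoint
#'   intervals.
#' @export
breakpoint_interval <- function(start, end, positions, ok, chrom_length) {
  stopifnot(length(positions) == length(ok))
  left_flank <- positions[ok & positions < start]
  right_flank <- positions[ok & positions > end]
  left <- if (length(left_flank)) c(max(left_flank), start) else c(1, start)
  right <- if (length(right_flank)) c(end, min(right_flank))
           else c(end, chrom_length)
  list(left = left, right = right)
}

#' Relation of an event region to the centromere
#'
#' `spans` when the region strictly contains the whole centromere interval;
#' otherwise `breakpoint_at_centromere` when either breakpoint interval lies
#' within `proximity_window` of the centromere; `none` otherwise.
#'
#' @param region_start,region_end Event region in bp.
#' @param breakpoints List of breakpoint intervals from
#'   [breakpoint_interval()] (may be `NULL`, then region edges are used).
#' @param model One row of a chromosome model table.
#' @param proximity_window Distance in bp (default 1e6).
#' @return One of `"spans"`, `"breakpoint_at_centromere"`, `"none"`.
#' @export
annotate_centromere <- function(region_start, region_end, model,
                                breakpoints = NULL, proximity_window = 1e6) {
  cs <- model$centromere_start; ce <- model$centromere_end
  if (region_start < cs && region_end > ce) return("spans")
  if (is.null(breakpoints)) {
    breakpoints <- list(c(region_start, region_start),
                        c(region_end, region_end))
  }
  near <- function(iv) {
    ## distance between interval iv and the centromere interval
    d <- max(0, max(cs - iv[2L], iv[1L] - ce))
    d <= proximity_window
  }
  if (any(vapply(breakpoints, near, logical(1L)))) {
    return("breakpoint_at_centromere")
  }
  "none"
}

#' Full event-detection pipeline for one population
#'
#' Runs dosage derivation, run finding, aneuploidy detection, reciprocal
#' matching, inheritance classification, size/breakpoint/centromere
#' annotation, in that order.
#'
#' @param calls Genotype call table from [call_genotypes()] (progeny only).
#' @param markers Marker classification table from [call_genotypes()].
#' @param marker_map Table with `probe_id`, `chromosome`, `position`.
#' @param map Homoeology block table.
#' @param chrom_models Chromosome model table (see
#'   [default_chromosome_models()]).
#' @param min_run,gap_tolerance See [find_aberrant_runs()].
#' @param aneuploid_fraction See [detect_aneuploidy()].
#' @param overlap_fraction See [classify_inheritance()].
#' @param population_size Number of progeny; default the number of distinct
#'   individuals in `calls`.
#' @return Event table with columns of [match_reciprocal()] plus
#'   `inheritance`, `size_mb_gain`, `size_mb_loss`, `centromere_relation`,
#'   `low_confidence` (TRUE when any side has fewer than 10 supporting
#'   loci).
#' @export
detect_events <- function(calls, markers, marker_map, map, chrom_models,
                          min_run = 3L, gap_tolerance = 1L,
                          aneuploid_fraction = 0.95, overlap_fraction = 0.5,
                          population_size = NULL) {
  calls <- data.table::as.data.table(calls)
  markers <- data.table::as.data.table(markers)
  marker_map <- data.table::as.data.table(marker_map)
  if (is.null(population_size)) {
    population_size <- length(unique(calls$individual_id))
  }
  ## informative = polymorphic non-dual markers with known orientation
  info <- markers[!is.na(aa_parent), .(probe_id, aa_parent)]
  dc <- merge(calls, info, by = "probe_id")
  dc <- merge(dc, marker_map[, .(probe_id, chromosome, position)],
              by = "probe_id")
  dc[, dosage := derive_dosage(genotype, aa_parent)]
  runs <- find_runs_by_individual(dc, min_run = min_run,
                                  gap_tolerance = gap_tolerance)
  ## scorable loci per individual and chromosome: informative markers with
  ## a usable (non-unknown) dosage call
  ic <- dc[dosage != "unknown", .(n_informative = .N),
           by = .(individual_id, chromosome)]
  split_runs <- detect_aneuploidy(runs, ic,
                                  aneuploid_fraction = aneuploid_fraction)
  ev_aneu <- aneuploid_events(split_runs$aneuploid, chrom_models)
  seg <- split_runs$segmental
  ev_seg <- if (nrow(seg)) {
    data.table::rbindlist(lapply(split(seg, seg$individual_id),
                                 match_reciprocal, map = map,
                                 min_support = min_run))
  } else empty_event_table()
  events <- data.table::rbindlist(list(ev_seg, ev_aneu), use.names = TRUE,
                                  fill = TRUE)
  if (nrow(events) == 0L) {
    events <- empty_event_table()
    events[, `:=`(inheritance = character(), size_mb_gain = numeric(),
                  size_mb_loss = numeric(),
                  centromere_relation = character(),
                  low_confidence = logical())]
    return(events[])
  }
  events <- classify_inheritance(events, population_size,
                                 overlap_fraction = overlap_fraction)
  events[, `:=`(
    size_mb_gain = (gain_end - gain_start + 1) / 1e6,
    size_mb_loss = (loss_end - loss_start + 1) / 1e6
  )]
  events[, low_confidence :=
           (data.table::fcoalesce(n_support_gain, 10L) < 10L) |
           (data.table::fcoalesce(n_support_loss, 10L) < 10L)]
  events[, centromere_relation := centromere_relation_of(.SD, chrom_models)]
  events[, event_id := sprintf("ev_%04d", seq_len(.N))]
  data.table::setcolorder(events, "event_id")
  events[]
}

## internal: aneuploid run rows -> event rows spanning the whole chromosome
aneuploid_events <- function(aneu, chrom_models) {
  if (nrow(aneu) == 0L) return(empty_event_table())
  cm <- data.table::as.data.table(chrom_models)
  rows <- lapply(seq_len(nrow(aneu)), function(i) {
    chrom <- aneu$chromosome[i]
    len <- cm$length[cm$chromosome == chrom]
    len <- if (length(len)) len else aneu$end[i]
    gain <- aneu$direction[i] == "gain"
    data.table::data.table(
      type = if (gain) "aneuploid_gain" else "aneuploid_loss",
      gain_chrom = if (gain) chrom else NA_character_,
      gain_start = if (gain) 1 else NA_real_,
      gain_end = if (gain) as.numeric(len) else NA_real_,
      n_support_gain = if (gain) aneu$n_support[i] else NA_integer_,
      loss_chrom = if (gain) NA_character_ else chrom,
      loss_start = if (gain) NA_real_ else 1,
      loss_end = if (gain) NA_real_ else as.numeric(len),
      n_support_loss = if (gain) NA_integer_ else aneu$n_support[i],
      parent_of_origin = aneu$parent_of_origin[i],
      individual_id = aneu$individual_id[i],
      flagged = FALSE
    )
  })
  data.table::rbindlist(rows)
}

## internal: per-event centromere relation using the primary (gain, else
## loss) region
centromere_relation_of <- function(events, chrom_models) {
  cm <- data.table::as.data.table(chrom_models)
  vapply(seq_len(nrow(events)), function(i) {
    chrom <- events$gain_chrom[i]
    s <- events$gain_start[i]; e <- events$gain_end[i]
    if (is.na(chrom)) {
      chrom <- events$loss_chrom[i]
      s <- events$loss_start[i]; e <- events$loss_end[i]
    }
    m <- cm[chromosome == chrom]
    if (nrow(m) == 0L) return("none")
    annotate_centromere(s, e, m)
  }, character(1L))
}

#' Score detected events against a planted truth catalogue
#'
#' A detected event matches a truth event when the types agree (HeR matches
#' HeR, deletion matches deletion, etc.), the individual agrees, and every
#' region present in the truth event reciprocally overlaps the corresponding
#' detected region by at least `overlap_fraction`.
#'
#' @param detected Event table from [detect_events()].
#' @param truth Truth catalogue from [simulate_population()].
#' @param overlap_fraction Reciprocal overlap threshold (default 0.5).
#' @param min_truth_support Only truth events whose regions are supported by
#'   at least this many informative loci count toward sensitivity
#'   (default 1).
#' @return A list: `sensitivity`, `fdr`, `n_truth`, `n_detected`,
#'   `matched_truth`, `matched_detected` (logical vectors).
#' @export
score_recovery <- function(detected, truth, overlap_fraction = 0.5,
                           min_truth_support = 1L) {
  detected <- data.table::as.data.table(detected)
  truth <- data.table::as.data.table(truth)
  region_match <- function(ti, di) {
    if (truth$type[ti] != detected$type[di]) return(FALSE)
    if (truth$individual_id[ti] != detected$individual_id[di]) return(FALSE)
    for (side in c("gain", "loss")) {
      tc <- truth[[paste0(side, "_chrom")]][ti]
      if (is.na(tc)) next
      dc <- detected[[paste0(side, "_chrom")]][di]
      if (is.na(dc) || dc != tc) return(FALSE)
      r1 <- c(truth[[paste0(side, "_start")]][ti],
              truth[[paste0(side, "_end")]][ti])
      r2 <- c(detected[[paste0(side, "_start")]][di],
              detected[[paste0(side, "_end")]][di])
      if (!reciprocal_overlap_ok(r1, r2, overlap_fraction)) return(FALSE)
    }
    TRUE
  }
  eligible <- truth$n_support >= min_truth_support
  matched_truth <- rep(FALSE, nrow(truth))
  matched_det <- rep(FALSE, nrow(detected))
  for (ti in seq_len(nrow(truth))) {
    for (di in seq_len(nrow(detected))) {
      if (region_match(ti, di)) {
        matched_truth[ti] <- TRUE
        matched_det[di] <- TRUE
      }
    }
  }
  sens <- if (any(eligible)) mean(matched_truth[eligible]) else NA_real_
  fdr <- if (nrow(detected)) mean(!matched_det) else 0
  list(sensitivity = sens, fdr = fdr,
       n_truth = sum(eligible), n_detected = nrow(detected),
       matched_truth = matched_truth, matched_detected = matched_det)
}

#' Write and read event tables
#'
#' Events are serialised as TSV (all fields, lossless round-trip) and as
#' BED6+ with one row per affected region; HeR events emit paired rows
#' sharing the event id.
#'
#' @param events Event table.
#' @param file Output path.
#' @return Invisibly, the file path; `read_events_tsv()` returns the event
#'   `data.table`.
#' @export
write_events_tsv <- function(events, file) {
  write_tsv_commented(data.table::as.data.table(events), file)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(file) {
  dt <- read_tsv_commented(file)
  for (col in c("gain_chrom", "loss_chrom", "individual_id",
                "parent_of_origin", "inheritance")) {
    if (col %in% names(dt)) dt[[col]] <- as.character(dt[[col]])
  }
  data.table::as.data.table(dt)
}

#' @rdname write_events_tsv
#' @export
write_events_bed <- function(events, file) {
  events <- data.table::as.data.table(events)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    id <- if ("event_id" %in% names(events)) events$event_id[i]
          else sprintf("ev_%04d", i)
    for (side in c("gain", "loss")) {
      chrom <- events[[paste0(side, "_chrom")]][i]
      if (is.na(chrom)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = chrom,
        start = as.integer(events[[paste0(side, "_start")]][i]) - 1L,
        end = as.integer(events[[paste0(side, "_end")]][i]),
        name = paste0(id, ":", events$type[i], ":", side),
        score = 0L,
        strand = if (side == "gain") "+" else "-"
      )
    }
  }
  bed <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table()
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
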