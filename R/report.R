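#' Summarise de novo events per line
#'
#' One row per line parent plus one row for the common tester, with counts
#' of duplications, deletions, HeR events (counted once per event) and
#' aneuploid events (one per chromosome affected), and their total.  Events
#' with an unknown parent of origin are tallied in an `unattributed` row,
#' never dropped.
#'
#' @param events Event table (see [detect_events()]); typically filtered to
#'   `inheritance == "de_novo"` upstream — rows of other inheritance classes
#'   are excluded here.
#' @param populations Population metadata: `line_id`, `n_individuals`, and
#'   optionally `tester` (single common tester name; default "tester").
#' @return A `data.table`: `line_id`, `n_individuals`, `duplication`,
#'   `deletion`, `her`, `aneuploid`, `total`.
#' @export
summarize_by_line <- function(events, populations) {
  ev <- de_novo_only(events)
  pop <- data.table::as.data.table(populations)
  tester <- if ("tester" %in% names(pop)) pop$tester[1L] else "tester"
  parents <- c(pop$line_id, tester)
  ev[, parent := data.table::fifelse(
    is.na(parent_of_origin) | !parent_of_origin %in% parents,
    "unattributed", parent_of_origin)]
  cnt <- ev[, .(
    duplication = sum(type == "duplication"),
    deletion = sum(type == "deletion"),
    her = sum(type == "her"),
    aneuploid = sum(type %in% c("aneuploid_gain", "aneuploid_loss"))
  ), by = parent]
  base <- data.table::data.table(
    line_id = parents,
    n_individuals = c(pop$n_individuals, sum(pop$n_individuals)))
  out <- merge(base, cnt, by.x = "line_id", by.y = "parent", all.x = TRUE,
               sort = FALSE)
  if ("unattributed" %in% cnt$parent) {
    out <- rbind(out, data.table::data.table(
      line_id = "unattributed", n_individuals = NA_integer_,
      cnt[parent == "unattributed", !"parent"]))
  }
  for (col in c("duplication", "deletion", "her", "aneuploid")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, total := duplication + deletion + her + aneuploid]
  out[]
}

#' Summarise de novo events per chromosome
#'
#' HeR events contribute one `her_gain` on the gained chromosome and one
#' `her_loss` on the lost chromosome; duplications, deletions and aneuploid
#' events count on their affected chromosome.  A `TOTAL` row is appended;
#' the her_gain and her_loss grand totals are always equal since each HeR
#' emits one of each.
#'
#' @param events Event table (de novo rows are used).
#' @return A `data.table`: `chromosome`, `duplication`, `deletion`,
#'   `her_gain`, `her_loss`, `aneuploid`, `total`.
#' @export
summarize_by_chromosome <- function(events) {
  ev <- de_novo_only(events)
  if (nrow(ev) == 0L) {
    return(data.table::data.table(
      chromosome = character(), duplication = integer(),
      deletion = integer(), her_gain = integer(), her_loss = integer(),
      aneuploid = integer(), total = integer()))
  }
  tab <- function(chroms) {
    chroms <- chroms[!is.na(chroms)]
    if (length(chroms) == 0L) {
      return(data.table::data.table(chromosome = character(),
                                    n = integer()))
    }
    x <- table(chroms)
    data.table::data.table(chromosome = names(x), n = as.integer(x))
  }
  pieces <- list(
    duplication = tab(ev[type == "duplication", gain_chrom]),
    deletion = tab(ev[type == "deletion", loss_chrom]),
    her_gain = tab(ev[type == "her", gain_chrom]),
    her_loss = tab(ev[type == "her", loss_chrom]),
    aneuploid = tab(c(ev[type == "aneuploid_gain", gain_chrom],
                      ev[type == "aneuploid_loss", loss_chrom]))
  )
  chroms <- sort(unique(unlist(lapply(pieces, `[[`, "chromosome"))))
  out <- data.table::data.table(chromosome = chroms)
  for (nm in names(pieces)) {
    out <- merge(out, data.table::setnames(pieces[[nm]], "n", nm),
                 by = "chromosome", all.x = TRUE, sort = FALSE)
    data.table::set(out, which(is.na(out[[nm]])), nm, 0L)
  }
  ## natural karyotype order when names follow A1..C9
  ord <- order(substr(out$chromosome, 1, 1),
               suppressWarnings(as.integer(sub("^[AC]", "",
                                               out$chromosome))))
  out <- out[ord]
  out[, total := duplication + deletion + her_gain + her_loss + aneuploid]
  totals <- out[, lapply(.SD, sum), .SDcols = !"chromosome"]
  rbind(out, data.table::data.table(chromosome = "TOTAL", totals))
}

de_novo_only <- function(events) {
  ev <- data.table::as.data.table(events)
  if ("inheritance" %in% names(ev)) ev <- ev[inheritance == "de_novo"]
  ev
}

#' Derived genome-level statistics from an event catalogue
#'
#' Computes the headline statistics of a testcross event catalogue:
#' subgenome bias of HeR gains, the contribution of a named homoeologue
#' pair, aneuploidy totals, per-subgenome deletion and gain/loss tallies
#' (including aneuploid additions and losses), the distinct de novo event
#' count (each HeR counted once) and the number of meioses assayed
#' (two per testcross individual).  Percentages matched against prose are
#' reported floored to integer percent, with the exact fraction alongside.
#' With no HeR events the share statistics are `NA` (undefined), not 0.
#'
#' @param events Event table (de novo rows are used).
#' @param populations Optional population metadata (as in
#'   [summarize_by_line()]); required for the meioses statistic.
#' @param pair Two chromosome names forming the homoeologue pair of interest
#'   (default `c("A1", "C1")`).
#' @return A named list of statistics; `mb` holds Mb gained/lost per
#'   chromosome and category when event sizes are present.
#' @export
derived_statistics <- function(events, populations = NULL,
                               pair = c("A1", "C1")) {
  ev <- de_novo_only(events)
  her <- ev[type == "her"]
  n_her <- nrow(her)
  gain_a <- sum(chromosome_subgenome(her$gain_chrom) == "A")
  dup <- ev[type == "duplication"]
  del <- ev[type == "deletion"]
  aneu_gain <- ev[type == "aneuploid_gain"]
  aneu_loss <- ev[type == "aneuploid_loss"]
  n_aneu <- nrow(aneu_gain) + nrow(aneu_loss)
  pair_n <- sum((her$gain_chrom == pair[1L] & her$loss_chrom == pair[2L]) |
                  (her$gain_chrom == pair[2L] & her$loss_chrom == pair[1L]))
  aneu_chrom <- c(aneu_gain$gain_chrom, aneu_loss$loss_chrom)
  sub_of <- chromosome_subgenome
  gains_a <- sum(sub_of(dup$gain_chrom) == "A") + gain_a +
    sum(sub_of(aneu_gain$gain_chrom) == "A")
  gains_c <- sum(sub_of(dup$gain_chrom) == "C") + (n_her - gain_a) +
    sum(sub_of(aneu_gain$gain_chrom) == "C")
  losses_a <- sum(sub_of(del$loss_chrom) == "A") +
    sum(sub_of(her$loss_chrom) == "A") +
    sum(sub_of(aneu_loss$loss_chrom) == "A")
  losses_c <- sum(sub_of(del$loss_chrom) == "C") +
    sum(sub_of(her$loss_chrom) == "C") +
    sum(sub_of(aneu_loss$loss_chrom) == "C")
  meioses <- if (!is.null(populations)) {
    2L * sum(data.table::as.data.table(populations)$n_individuals)
  } else NA_integer_
  pct_floor <- function(num, den) {
    if (den == 0) NA_real_ else floor(100 * num / den)
  }
  stats <- list(
    n_her = n_her,
    her_gain_a = gain_a,
    her_gain_a_share_pct = pct_floor(gain_a, n_her),
    her_gain_a_share = if (n_her) gain_a / n_her else NA_real_,
    pair = paste(pair, collapse = "/"),
    pair_her_count = pair_n,
    pair_her_pct = pct_floor(pair_n, n_her),
    aneuploid_total = n_aneu,
    aneuploid_on_pair_chroms = sum(aneu_chrom %in%
                                     c("A1", "A2", "C1", "C2")),
    gain_or_loss_only = nrow(dup) + nrow(del) + n_aneu,
    deletions_total = nrow(del),
    deletions_a = sum(sub_of(del$loss_chrom) == "A"),
    deletions_c = sum(sub_of(del$loss_chrom) == "C"),
    de_novo_events = n_her + nrow(dup) + nrow(del) + n_aneu,
    gains_a_incl_aneuploid = gains_a,
    gains_c_incl_aneuploid = gains_c,
    losses_a_incl_aneuploid = losses_a,
    losses_c_incl_aneuploid = losses_c,
    meioses = meioses
  )
  stats$mb <- summarize_mb(ev)
  stats
}

#' Mb gained and lost per chromosome per event category
#'
#' Sizes are event spans between outermost affected probes, in Mb; rows
#' with missing sizes are ignored.
#'
#' @param events Event table with `size_mb_gain` / `size_mb_loss` columns
#'   (or gain/loss start/end columns from which they are computed).
#' @return A `data.table`: `chromosome`, `category` (duplication, deletion,
#'   her_gain, her_loss, aneuploid_gain, aneuploid_loss), `mb`.
#' @export
summarize_mb <- function(events) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) {
    return(data.table::data.table(chromosome = character(),
                                  category = character(), mb = numeric()))
  }
  if (!"size_mb_gain" %in% names(ev)) {
    ev[, size_mb_gain := (gain_end - gain_start + 1) / 1e6]
    ev[, size_mb_loss := (loss_end - loss_start + 1) / 1e6]
  }
  gain_cat <- c(her = "her_gain", duplication = "duplication",
                aneuploid_gain = "aneuploid_gain")
  loss_cat <- c(her = "her_loss", deletion = "deletion",
                aneuploid_loss = "aneuploid_loss")
  g <- ev[type %in% names(gain_cat) & !is.na(size_mb_gain),
          .(mb = sum(size_mb_gain)),
          by = .(chromosome = gain_chrom, category = gain_cat[type])]
  l <- ev[type %in% names(loss_cat) & !is.na(size_mb_loss),
          .(mb = sum(size_mb_loss)),
          by = .(chromosome = loss_chrom, category = loss_cat[type])]
  out <- rbind(g, l)
  data.table::setorder(out, chromosome, category)
  out[]
}

#' Support-loci and size summary of an event catalogue
#'
#' Reports, over all affected regions, how many are defined by at least
#' `min_loci` supporting loci, and the smallest and largest event sizes per
#' type.  An HeR event contributes two regions (gain and loss).
#'
#' @param events Event table with `n_support_gain` / `n_support_loss` and
#'   size columns.
#' @param min_loci Threshold for the well-supported count (default 10).
#' @return A list: `n_regions`, `n_regions_min_loci`, `fraction`,
#'   `min_size_mb` and `max_size_mb` (named by event type).
#' @export
summarize_event_support <- function(events, min_loci = 10L) {
  ev <- data.table::as.data.table(events)
  sup <- c(ev$n_support_gain[!is.na(ev$n_support_gain)],
           ev$n_support_loss[!is.na(ev$n_support_loss)])
  if (!"size_mb_gain" %in% names(ev)) {
    ev[, size_mb_gain := (gain_end - gain_start + 1) / 1e6]
    ev[, size_mb_loss := (loss_end - loss_start + 1) / 1e6]
  }
  sizes <- ev[, .(size = c(size_mb_gain, size_mb_loss)), by = type]
  sizes <- sizes[!is.na(size)]
  rng <- sizes[, .(min = min(size), max = max(size)), by = type]
  list(
    n_regions = length(sup),
    n_regions_min_loci = sum(sup >= min_loci),
    fraction = if (length(sup)) sum(sup >= min_loci) / length(sup)
               else NA_real_,
    min_size_mb = stats::setNames(rng$min, rng$type),
    max_size_mb = stats::setNames(rng$max, rng$type)
  )
}

#' Bundled reference event catalogue of a B. napus testcross experiment
#'
#' A per-event expansion of the published de novo event counts from ten
#' spring-type *B. napus* testcross populations crossed to the common tester
#' Rainbow (254 individuals, 508 meioses): 36 HeR events, 26 duplications,
#' 42 deletions and 25 aneuploid events (13 additions, 12 losses).  The
#' per-line and per-chromosome margins, the A1/C1 concentration of HeR (17
#' events), the A9 pairings (3 with C8, 2 with C9) and the known aneuploid
#' individuals (an extra A7 plus C6 inherited from Rainbow by one Maris
#' Haplona individual; an extra C9 in one Zhongyou821 individual) follow the
#' published tallies exactly.  The joint line-by-chromosome placement of the
#' remaining events is not published; it is reconstructed here by a
#' deterministic fill that preserves all margins, so per-event rows are
#' synthetic in that respect.  Positions and sizes are not published per
#' event and are `NA`.
#'
#' @return An event `data.table` in the [detect_events()] schema (positions
#'   `NA`), with `population_id` and `inheritance = "de_novo"`.
#' @export
reference_event_catalog <- function() {
  her <- rbind(
    expand_events("her", "PAK85912", "A1", "C1", 4),
    expand_events("her", "PAK85912", "C1", "A1", 1),
    expand_events("her", "Daichousen", "A1", "C1", 1),
    expand_events("her", "Rainbow", "A1", "C1", 8),
    expand_events("her", "Rainbow", "C1", "A1", 3),
    expand_events("her", "Rainbow", "A2", "C2", 1),
    expand_events("her", "Rainbow", "C2", "A2", 1),
    expand_events("her", "Rainbow", "A3", "C3", 2),
    expand_events("her", "Rainbow", "C3", "A3", 3),
    expand_events("her", "Rainbow", "A4", "C4", 2),
    expand_events("her", "Rainbow", "A5", "C4", 1),
    expand_events("her", "Rainbow", "A5", "C5", 2),
    expand_events("her", "Rainbow", "C5", "A5", 2),
    expand_events("her", "Rainbow", "A9", "C8", 2),
    expand_events("her", "Rainbow", "C8", "A9", 1),
    expand_events("her", "Rainbow", "A9", "C9", 1),
    expand_events("her", "Rainbow", "C9", "A9", 1)
  )
  dup <- rbind(
    expand_events("duplication", "ACSRsyn1", "A1", NA, 2),
    expand_events("duplication", "MarisHaplona", "A1", NA, 1),
    expand_events("duplication", "SvalofsGulle", "A2", NA, 1),
    expand_events("duplication", "Tribune", "A2", NA, 2),
    expand_events("duplication", "PAK85912", "A4", NA, 1),
    expand_events("duplication", "PAK85912", "A5", NA, 4),
    expand_events("duplication", "Zhongyou821", "A5", NA, 2),
    expand_events("duplication", "Zhongyou821", "A6", NA, 1),
    expand_events("duplication", "Rainbow", "A7", NA, 1),
    expand_events("duplication", "Rainbow", "A9", NA, 2),
    expand_events("duplication", "Rainbow", "C2", NA, 2),
    expand_events("duplication", "Rainbow", "C3", NA, 3),
    expand_events("duplication", "Rainbow", "C6", NA, 1),
    expand_events("duplication", "Rainbow", "C7", NA, 1),
    expand_events("duplication", "Rainbow", "C8", NA, 2)
  )
  del <- rbind(
    expand_events("deletion", "ACSRsyn1", NA, "A1", 1),
    expand_events("deletion", "ACSRsyn1", NA, "A2", 1),
    expand_events("deletion", "Bronowski", NA, "A2", 1),
    expand_events("deletion", "MarisHaplona", NA, "A2", 4),
    expand_events("deletion", "MarisHaplona", NA, "A3", 3),
    expand_events("deletion", "MarisHaplona", NA, "A4", 1),
    expand_events("deletion", "Tribune", NA, "A5", 1),
    expand_events("deletion", "Tribune", NA, "A6", 1),
    expand_events("deletion", "Topas", NA, "A6", 1),
    expand_events("deletion", "PAK85912", NA, "A7", 3),
    expand_events("deletion", "PAK85912", NA, "A8", 1),
    expand_events("deletion", "Zhongyou821", NA, "A9", 2),
    expand_events("deletion", "Rainbow", NA, "A9", 5),
    expand_events("deletion", "Rainbow", NA, "A10", 2),
    expand_events("deletion", "Rainbow", NA, "C1", 3),
    expand_events("deletion", "Rainbow", NA, "C2", 2),
    expand_events("deletion", "Rainbow", NA, "C3", 1),
    expand_events("deletion", "Rainbow", NA, "C5", 2),
    expand_events("deletion", "Rainbow", NA, "C6", 2),
    expand_events("deletion", "Rainbow", NA, "C7", 2),
    expand_events("deletion", "Rainbow", NA, "C8", 2),
    expand_events("deletion", "Rainbow", NA, "C9", 1)
  )
  aneu <- rbind(
    expand_events("aneuploid_gain", "Daichousen", "A1", NA, 1),
    expand_events("aneuploid_gain", "MarisHaplona", "A2", NA, 1),
    expand_events("aneuploid_gain", "SvalofsGulle", "A2", NA, 1),
    expand_events("aneuploid_gain", "Tribune", "A5", NA, 1),
    expand_events("aneuploid_loss", "Topas", NA, "A2", 1),
    expand_events("aneuploid_loss", "PAK85912", NA, "A2", 1),
    expand_events("aneuploid_loss", "PAK85912", NA, "A4", 1),
    expand_events("aneuploid_loss", "PAK85912", NA, "A5", 1),
    expand_events("aneuploid_gain", "Zhongyou821", "C9", NA, 1),
    expand_events("aneuploid_loss", "Zhongyou821", NA, "A10", 1),
    expand_events("aneuploid_loss", "Zhongyou821", NA, "C1", 1),
    expand_events("aneuploid_loss", "Zhongyou821", NA, "C2", 1),
    expand_events("aneuploid_gain", "Rainbow", "A7", NA, 2),
    expand_events("aneuploid_gain", "Rainbow", "A8", NA, 3),
    expand_events("aneuploid_gain", "Rainbow", "C2", NA, 2),
    expand_events("aneuploid_gain", "Rainbow", "C6", NA, 1),
    expand_events("aneuploid_loss", "Rainbow", NA, "C2", 2),
    expand_events("aneuploid_loss", "Rainbow", NA, "C7", 1),
    expand_events("aneuploid_loss", "Rainbow", NA, "C8", 2)
  )
  ev <- rbind(her, dup, del, aneu)
  lines <- reference_populations()$line_id
  ## population: the line itself for line-parent events; round-robin over
  ## the ten populations for tester-meiosis events (not published per event)
  is_tester <- ev$parent_of_origin == "Rainbow"
  ev[, population_id := parent_of_origin]
  ev$population_id[is_tester] <- rep(lines,
                                     length.out = sum(is_tester))
  ev[, individual_id := paste0(population_id, "_", seq_len(.N))]
  ## known double-aneuploid tester individual and Zhongyou821 extra C9
  m19 <- which(ev$parent_of_origin == "Rainbow" &
                 ev$type == "aneuploid_gain" &
                 (ev$gain_chrom %in% c("A7", "C6")))
  if (length(m19) >= 2L) {
    m19 <- c(which(ev$gain_chrom == "A7" & ev$type == "aneuploid_gain" &
                     ev$parent_of_origin == "Rainbow")[1L],
             which(ev$gain_chrom == "C6" & ev$type == "aneuploid_gain" &
                     ev$parent_of_origin == "Rainbow")[1L])
    ev$population_id[m19] <- "MarisHaplona"
    ev$individual_id[m19] <- "MarisHaplona_19"
  }
  z26 <- which(ev$type == "aneuploid_gain" & ev$gain_chrom == "C9")
  if (length(z26)) ev$individual_id[z26[1L]] <- "Zhongyou821_26"
  ev[, inheritance := "de_novo"]
  ev[, event_id := sprintf("ref_%03d", seq_len(.N))]
  data.table::setcolorder(ev, "event_id")
  ev[]
}

expand_events <- function(type, parent, gain_chrom, loss_chrom, n) {
  data.table::data.table(
    type = type,
    gain_chrom = rep(as.character(gain_chrom), n),
    gain_start = NA_real_, gain_end = NA_real_,
    n_support_gain = NA_integer_,
    loss_chrom = rep(as.character(loss_chrom), n),
    loss_start = NA_real_, loss_end = NA_real_,
    n_support_loss = NA_integer_,
    parent_of_origin = parent, flagged = FALSE
  )
}

#' @rdname reference_event_catalog
#' @export
reference_populations <- function() {
  data.table::data.table(
    line_id = c("ACSRsyn1", "Bronowski", "Daichousen", "MarisHaplona",
                "Surpass400", "SvalofsGulle", "Tribune", "Topas",
                "PAK85912", "Zhongyou821"),
    n_individuals = c(16L, 16L, 16L, 48L, 16L, 16L, 16L, 16L, 46L, 48L),
    tester = "Rainbow"
  )
}
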