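#' Normalise windowed read depth per chromosome
#'
#' Each chromosome's windows are divided by the chromosome centre (mean, or
#' median when `robust = TRUE`) so that a euploid chromosome sits at 1.0
#' regardless of sequencing depth.  The chromosome noise scale used for
#' segmentation is estimated robustly (median centre, scaled MAD) so that
#' large true events — which can cover a fifth of a chromosome or more —
#' cannot inflate the null SD and mask themselves; a degenerate MAD of zero
#' falls back to a one-pass 3-SD-trimmed SD.
#'
#' @param windows Table with columns `chromosome`, `start`, `end`,
#'   `raw_depth` (windows tile each chromosome without overlap).
#' @param robust Use the median instead of the mean as the chromosome centre
#'   (default FALSE, matching mean-centred normalisation).
#' @return The windows with `normalized_depth` and `z` columns added; the
#'   per-chromosome centre and SD are attached as attribute `"scale"`
#'   (a `data.table` with `chromosome`, `center`, `norm_mean`, `norm_sd`).
#' @export
normalize_depth <- function(windows, robust = FALSE) {
  dt <- data.table::as.data.table(windows)
  stopifnot(all(c("chromosome", "start", "end", "raw_depth") %in% names(dt)))
  if (any(dt$raw_depth < 0)) stop("raw_depth must be >= 0")
  center_fun <- if (robust) stats::median else mean
  scale <- dt[, .(center = center_fun(raw_depth)), by = chromosome]
  if (any(scale$center <= 0)) {
    stop("chromosome with zero coverage: ",
         paste(scale$chromosome[scale$center <= 0], collapse = ", "))
  }
  dt <- merge(dt, scale, by = "chromosome", sort = FALSE)
  dt[, normalized_depth := raw_depth / center]
  trimmed <- dt[, {
    m <- stats::median(normalized_depth)
    s <- stats::mad(normalized_depth, center = m)
    if (!is.finite(s) || s == 0) {
      ## fall back to a one-pass 3-SD trim for (near-)degenerate profiles
      m0 <- mean(normalized_depth); s0 <- stats::sd(normalized_depth)
      keep <- if (is.na(s0) || s0 == 0) rep(TRUE, .N) else
        abs(normalized_depth - m0) <= 3 * s0
      m <- mean(normalized_depth[keep])
      s <- stats::sd(normalized_depth[keep])
    }
    .(norm_mean = m, norm_sd = s)
  }, by = chromosome]
  dt <- merge(dt, trimmed, by = "chromosome", sort = FALSE)
  dt[, z := data.table::fifelse(
    is.finite(norm_sd) & norm_sd > 0,
    (normalized_depth - norm_mean) / norm_sd, 0)]
  data.table::setorder(dt, chromosome, start)
  scale <- merge(scale, trimmed, by = "chromosome")
  out <- dt[, .(chromosome, start, end, raw_depth, normalized_depth, z)]
  data.table::setattr(out, "scale", scale)
  out
}

#' Call depth-deviant segments at an SD threshold
#'
#' Maximal runs of at least `min_windows` consecutive windows all deviating
#' by at least `sd_multiplier` chromosome SDs from the chromosomal mean, in
#' the same direction, become segments; direction is `gain` above the mean
#' and `loss` below it.
#'
#' @param windows Normalised windows from [normalize_depth()].
#' @param sd_multiplier Deviation threshold in SD units (default 1.5).
#' @param min_windows Minimum consecutive windows per segment (default 5).
#' @return A `data.table` of segments: `chromosome`, `start`, `end`,
#'   `direction`, `mean_z`, `n_windows`.
#' @export
call_depth_segments <- function(windows, sd_multiplier = 1.5,
                                min_windows = 5L) {
  dt <- data.table::as.data.table(windows)
  stopifnot("z" %in% names(dt))
  data.table::setorder(dt, chromosome, start)
  segs <- dt[, {
    state <- data.table::fifelse(z >= sd_multiplier, 1L,
             data.table::fifelse(z <= -sd_multiplier, -1L, 0L))
    rl <- rle(state)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    sel <- which(rl$values != 0L & rl$lengths >= min_windows)
    if (length(sel)) {
      data.table::rbindlist(lapply(sel, function(k) {
        ix <- starts[k]:ends[k]
        data.table::data.table(
          start = start[ix[1L]], end = end[ix[length(ix)]],
          direction = if (rl$values[k] > 0L) "gain" else "loss",
          mean_z = mean(z[ix]), n_windows = length(ix))
      }))
    } else NULL
  }, by = chromosome]
  if (nrow(segs) == 0L) {
    segs <- data.table::data.table(
      chromosome = character(), start = numeric(), end = numeric(),
      direction = character(), mean_z = numeric(), n_windows = integer())
  }
  segs[]
}

#' Pair homoeologous gain/loss depth segments into fixed-HeR candidates
#'
#' A gain segment pairs with a loss segment from the opposite subgenome when
#' the projection of one through a homoeology block overlaps the other.
#' Paired segments are emitted as fixed-HeR candidate events; unpaired
#' segments are kept as unpaired gains/losses.
#'
#' @param segments Segment table from [call_depth_segments()].
#' @param map Homoeology block table from [build_homoeology_map()].
#' @return A `data.table`: `type` (`fixed_her_candidate` /
#'   `unpaired_gain` / `unpaired_loss`), gain and loss region columns.
#' @export
pair_homoeologous_segments <- function(segments, map) {
  seg <- data.table::as.data.table(segments)
  seg[, individual_id := "fixed"]
  seg[, parent_of_origin := "fixed"]
  seg[, n_support := n_windows]
  ev <- match_reciprocal(seg, map, min_support = 1L)
  ev[, type := data.table::fifelse(
    type == "her", "fixed_her_candidate",
    data.table::fifelse(type == "duplication", "unpaired_gain",
                        "unpaired_loss"))]
  ev[, c("individual_id", "parent_of_origin") := NULL]
  ev[]
}

#' Read a bedGraph or 4-column depth TSV
#'
#' bedGraph intervals are half-open 0-based; they are converted to 1-based
#' inclusive coordinates.  A plain TSV with header columns `chromosome`,
#' `start`, `end`, `raw_depth` (1-based inclusive) is accepted as-is.
#'
#' @param file Path to the file.
#' @return A `data.table` with `chromosome`, `start`, `end`, `raw_depth`.
#' @export
read_bedgraph <- function(file) {
  first <- readLines(file, n = 1L, warn = FALSE)
  has_header <- grepl("chromosome", first, fixed = TRUE)
  if (has_header) {
    dt <- read_tsv_commented(file)
    stopifnot(all(c("chromosome", "start", "end", "raw_depth") %in%
                    names(dt)))
    return(dt[, .(chromosome = as.character(chromosome),
                  start = as.numeric(start), end = as.numeric(end),
                  raw_depth = as.numeric(raw_depth))])
  }
  skip <- if (startsWith(first, "track") || startsWith(first, "#")) 1L else 0L
  dt <- data.table::fread(file, header = FALSE, sep = "\t", skip = skip)
  data.table::setnames(dt, 1:4, c("chromosome", "start", "end", "raw_depth"))
  dt[, .(chromosome = as.character(chromosome),
         start = as.numeric(start) + 1, end = as.numeric(end),
         raw_depth = as.numeric(raw_depth))]
}

#' @rdname read_bedgraph
#' @param windows Depth window table (1-based inclusive intervals).
#' @export
write_bedgraph <- function(windows, file) {
  dt <- data.table::as.data.table(windows)
  out <- dt[, .(chromosome, start = as.integer(start) - 1L,
                end = as.integer(end), raw_depth)]
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
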