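#' Chromosome models
#'
#' A chromosome model gives, for each chromosome, its name, length in bp and a
#' centromere interval.  Models are consumed by aneuploidy detection (which
#' needs informative-probe totals per chromosome), centromere annotation and
#' the depth simulator.
#'
#' `default_chromosome_models()` returns the 19 *B. napus* chromosomes
#' (A1-A10 from *B. rapa*, C1-C9 from *B. oleracea*) with marker-map spans
#' matching the array coverage of the Brassica 60K platform.  Centromere
#' intervals are a synthetic placeholder at 45-50% of each chromosome length:
#' real centromere coordinates are assembly-specific and must be supplied by
#' the user for centromere annotation to be meaningful.
#'
#' @param file Path to a tab-delimited chromosome model table with columns
#'   `chromosome`, `length`, `centromere_start`, `centromere_end`.  Header
#'   lines starting with `#` are ignored.
#' @return A `data.table` with columns `chromosome` (character), `length`
#'   (integer bp), `centromere_start`, `centromere_end` (integer bp).
#' @export
default_chromosome_models <- function() {
  len_mb <- c(
    A1 = 21.7, A2 = 29.6, A3 = 35.8, A4 = 21.1, A5 = 25.7,
    A6 = 26.1, A7 = 25.5, A8 = 21.7, A9 = 40.5, A10 = 17.9,
    C1 = 45.6, C2 = 47.3, C3 = 67.8, C4 = 55.1, C5 = 48.7,
    C6 = 40.8, C7 = 48.8, C8 = 44.7, C9 = 56.0
  )
  len <- as.integer(round(len_mb * 1e6))
  data.table::data.table(
    chromosome = names(len_mb),
    length = len,
    centromere_start = as.integer(round(0.45 * len)),
    centromere_end = as.integer(round(0.50 * len))
  )
}

#' @rdname default_chromosome_models
#' @export
read_chromosome_models <- function(file) {
  dt <- read_tsv_commented(file)
  need <- c("chromosome", "length", "centromere_start", "centromere_end")
  if (!all(need %in% names(dt))) {
    stop("chromosome model table must have columns: ",
         paste(need, collapse = ", "))
  }
  dt <- dt[, need, with = FALSE]
  bad <- dt$centromere_start < 1 | dt$centromere_end > dt$length |
    dt$centromere_start > dt$centromere_end
  if (any(bad)) stop("centromere interval outside [1, length] for: ",
                     paste(dt$chromosome[bad], collapse = ", "))
  dt
}

#' Subgenome of a chromosome name
#'
#' Chromosome names are expected to be prefixed with their subgenome letter
#' ("A1".."A10", "C1".."C9").
#'
#' @param chromosome Character vector of chromosome names.
#' @return Character vector of "A"/"C".
#' @export
chromosome_subgenome <- function(chromosome) {
  sg <- toupper(substr(chromosome, 1L, 1L))
  if (!all(sg %in% c("A", "C") | is.na(sg))) {
    stop("chromosome names must start with subgenome letter A or C")
  }
  sg
}

## internal: read a tab file skipping '#' comment lines (fread has no comment
## char); tolerates a commented header line '#col1\tcol2...'
read_tsv_commented <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_comment <- startsWith(lines, "#")
  if (all(is_comment)) stop("no data lines in ", file)
  first_data <- which(!is_comment)[1L]
  header <- NULL
  if (first_data > 1L) {
    ## last comment line before data may be a commented header
    cand <- sub("^#\\s*", "", lines[first_data - 1L])
    if (grepl("\t", cand) && !grepl("^[0-9]", cand)) header <- cand
  }
  body <- lines[!is_comment]
  txt <- paste(c(header, body), collapse = "\n")
  data.table::fread(text = txt, sep = "\t", header = TRUE, data.table = TRUE)
}

## internal: write a data.table as TSV with a '#'-prefixed header line
write_tsv_commented <- function(dt, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(dt), collapse = "\t")), con)
  utils::write.table(dt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
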