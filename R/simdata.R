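#' Simulation configuration for synthetic testcross populations
#'
#' Defaults encode the conditions observed in large *B. napus* testcross
#' experiments: roughly one in four meioses carries an event, split across
#' classes in proportion to published counts (HeR 36, deletions 42,
#' duplications 26, aneuploid gains 13 and losses 12 per 508 meioses;
#' terminal vs interstitial exchanges 61:43), the A genome is gained in two
#' thirds of HeR events, and about half the array markers are polymorphic in
#' a given cross.
#'
#' @param seed Integer seed; mandatory.  All stage streams are derived from
#'   it hierarchically so that adding individuals does not perturb earlier
#'   draws.
#' @param n_individuals Testcross progeny per population (default 20).
#' @param marker_map A list with `probes` and `blocks` as returned by
#'   [default_marker_map()].
#' @param rates Named per-meiosis event probabilities:
#'   `her_terminal`, `her_interstitial`, `deletion`, `duplication`,
#'   `aneuploid_gain`, `aneuploid_loss`; must sum to at most 1.
#' @param theta_centers Named theta cluster centres for the 8 states.
#' @param theta_noise_sd Gaussian theta noise SD (default 0.02).
#' @param r_noise_sd Multiplicative (lognormal) R noise SD (default 0.1).
#' @param nc_rate Fraction of progeny records dropped as missing
#'   (default 0.02).
#' @param fraction_monomorphic Fraction of markers monomorphic between the
#'   parents (default 0.5).
#' @param null_marker_rate Fraction of markers where one parent fails to
#'   amplify (default 0.02).
#' @param p_a_gain Probability that the A-genome side is the gained side of
#'   an HeR exchange (default 2/3).
#' @param min_event_probes Minimum informative loci each planted region must
#'   span; candidate events are redrawn (up to 20 times) until satisfied
#'   (default 10).
#' @param hemizygote_r_fraction,r_null R levels of single-allele and null
#'   states relative to full amplification.
#' @param depth_noise_sd Multiplicative noise SD of simulated read-depth
#'   windows (default 0.05).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_individuals = 20L,
                       marker_map = default_marker_map(),
                       rates = c(her_terminal = 0.042,
                                 her_interstitial = 0.029,
                                 deletion = 0.083,
                                 duplication = 0.051,
                                 aneuploid_gain = 0.026,
                                 aneuploid_loss = 0.024),
                       theta_centers = c(AA = 0.05, AAB = 0.275, AB = 0.5,
                                         ABB = 0.725, BB = 0.95,
                                         A0 = 0.05, B0 = 0.95, NC = 0.5),
                       theta_noise_sd = 0.02,
                       r_noise_sd = 0.1,
                       nc_rate = 0.02,
                       fraction_monomorphic = 0.5,
                       null_marker_rate = 0.02,
                       p_a_gain = 2 / 3,
                       min_event_probes = 10L,
                       hemizygote_r_fraction = 0.75,
                       r_null = 0.03,
                       depth_noise_sd = 0.05) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(all(rates >= 0), sum(rates) <= 1, theta_noise_sd >= 0,
            nc_rate >= 0, nc_rate < 1)
  structure(list(seed = as.integer(seed),
                 n_individuals = as.integer(n_individuals),
                 marker_map = marker_map, rates = rates,
                 theta_centers = theta_centers,
                 theta_noise_sd = theta_noise_sd, r_noise_sd = r_noise_sd,
                 nc_rate = nc_rate,
                 fraction_monomorphic = fraction_monomorphic,
                 null_marker_rate = null_marker_rate,
                 p_a_gain = p_a_gain,
                 min_event_probes = as.integer(min_event_probes),
                 hemizygote_r_fraction = hemizygote_r_fraction,
                 r_null = r_null, depth_noise_sd = depth_noise_sd),
            class = "sim_config")
}

## internal: hierarchical sub-seed in [1, 2^31 - 2]; deterministic in the
## master seed and a stream label
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

#' Default pseudo-tetraploid marker map
#'
#' Nineteen chromosomes mimicking the A1-A10 / C1-C9 karyotype with evenly
#' spaced probes, and homoeology blocks pairing Ai with Ci along their full
#' length for i = 1..8, while A9 and A10 pair with the top and bottom halves
#' of C9 respectively.
#'
#' @param n_probes_per_chrom Probes per chromosome (default 1000).
#' @param chrom_models Chromosome model table (default
#'   [default_chromosome_models()]).
#' @return A list: `probes` (`probe_id`, `chromosome`, `position`),
#'   `blocks` (homoeology block table as in [build_homoeology_map()]),
#'   `chrom_models`.
#' @export
default_marker_map <- function(n_probes_per_chrom = 1000L,
                               chrom_models = default_chromosome_models()) {
  cm <- data.table::as.data.table(chrom_models)
  probes <- cm[, {
    pos <- round(seq_len(n_probes_per_chrom) *
                   (length / (n_probes_per_chrom + 1)))
    .(probe_id = sprintf("%s_p%04d", chromosome, seq_len(n_probes_per_chrom)),
      position = as.integer(pos))
  }, by = chromosome]
  len <- stats::setNames(cm$length, cm$chromosome)
  blk <- function(a, as, ae, c, cs, ce) data.table::data.table(
    a_chrom = a, a_start = as, a_end = ae,
    c_chrom = c, c_start = cs, c_end = ce,
    orientation = "same", n_probes = n_probes_per_chrom)
  blocks <- data.table::rbindlist(c(
    lapply(1:8, function(i) blk(paste0("A", i), 1L, len[[paste0("A", i)]],
                                paste0("C", i), 1L, len[[paste0("C", i)]])),
    list(blk("A9", 1L, len[["A9"]], "C9", 1L, len[["C9"]] %/% 2L),
         blk("A10", 1L, len[["A10"]],
             "C9", len[["C9"]] %/% 2L + 1L, len[["C9"]]))
  ))
  blocks[, block_id := sprintf("blk_%03d", seq_len(.N))]
  data.table::setcolorder(blocks, "block_id")
  list(probes = probes[, .(probe_id, chromosome, position)],
       blocks = blocks[], chrom_models = cm)
}

#' Simulate one meiosis: gamete dosage vector plus planted events
#'
#' Each event class occurs independently with its per-meiosis rate.
#' Terminal HeR replaces one chromosome end with the homoeologous partner's
#' segment (one breakpoint, drawn uniformly within a block); interstitial
#' HeR uses two breakpoints; deletions and duplications plant unpaired loss
#' or gain intervals; aneuploidy toggles a whole chromosome.  Regions are
#' redrawn until they span at least `min_event_probes` informative loci and
#' do not overlap previously planted regions (`occupied`), keeping the truth
#' catalogue and the rendered genotypes mutually consistent.
#'
#' @param parent `"parent1"` or `"parent2"`.
#' @param config A [sim_config()].
#' @param informative Logical vector over `config$marker_map$probes`: which
#'   markers are informative (polymorphic, non-dual) in this cross.
#' @param seed Integer seed for this meiosis.
#' @param occupied Optional data.table of already-affected regions
#'   (`chromosome`, `start`, `end`) that new events must avoid.
#' @return A list: `dose` (integer vector over probes: 0 lost, 1 normal,
#'   2 duplicated), `events` (truth rows), `regions` (occupied regions after
#'   this meiosis).
#' @export
simulate_meiosis <- function(parent, config, informative, seed,
                             occupied = NULL) {
  probes <- config$marker_map$probes
  blocks <- config$marker_map$blocks
  cm <- config$marker_map$chrom_models
  rates <- config$rates
  if (sum(rates) > 1) stop("per-meiosis event rates must sum to <= 1")
  set.seed(seed)
  dose <- rep(1L, nrow(probes))
  events <- list()
  if (is.null(occupied)) {
    occupied <- data.table::data.table(chromosome = character(),
                                       start = numeric(), end = numeric())
  }
  n_info_in <- function(chrom, s, e) {
    sum(informative & probes$chromosome == chrom &
          probes$position >= s & probes$position <= e)
  }
  clash <- function(chrom, s, e) {
    any(occupied$chromosome == chrom & occupied$start <= e &
          occupied$end >= s)
  }
  apply_region <- function(chrom, s, e, d) {
    sel <- probes$chromosome == chrom & probes$position >= s &
      probes$position <= e
    dose[sel] <<- d
    occupied <<- rbind(occupied,
                       data.table::data.table(chromosome = chrom, start = s,
                                              end = e))
  }
  info_span <- function(chrom, s, e) {
    pos <- probes$position[informative & probes$chromosome == chrom &
                             probes$position >= s & probes$position <= e]
    c(min(pos), max(pos))
  }
  add_event <- function(type, gain = NULL, loss = NULL) {
    gs <- if (!is.null(gain)) info_span(gain[[1L]], gain[[2L]], gain[[3L]])
    ls <- if (!is.null(loss)) info_span(loss[[1L]], loss[[2L]], loss[[3L]])
    events[[length(events) + 1L]] <<- data.table::data.table(
      type = type,
      gain_chrom = if (is.null(gain)) NA_character_ else gain[[1L]],
      gain_start = if (is.null(gain)) NA_real_ else gs[1L],
      gain_end = if (is.null(gain)) NA_real_ else gs[2L],
      n_support_gain = if (is.null(gain)) NA_integer_ else
        n_info_in(gain[[1L]], gain[[2L]], gain[[3L]]),
      loss_chrom = if (is.null(loss)) NA_character_ else loss[[1L]],
      loss_start = if (is.null(loss)) NA_real_ else ls[1L],
      loss_end = if (is.null(loss)) NA_real_ else ls[2L],
      n_support_loss = if (is.null(loss)) NA_integer_ else
        n_info_in(loss[[1L]], loss[[2L]], loss[[3L]]),
      parent_of_origin = parent
    )
  }
  occurs <- stats::runif(length(rates)) < rates
  names(occurs) <- names(rates)

  her_event <- function(terminal) {
    for (try in 1:20) {
      blk <- blocks[sample(nrow(blocks), 1L)]
      a_gain <- stats::runif(1L) < config$p_a_gain
      if (terminal) {
        ## one breakpoint on the A side; exchange runs to a block end
        bp <- stats::runif(1L, blk$a_start, blk$a_end)
        to_end <- stats::runif(1L) < 0.5
        a_int <- if (to_end) c(bp, blk$a_end) else c(blk$a_start, bp)
      } else {
        bp <- sort(stats::runif(2L, blk$a_start, blk$a_end))
        a_int <- bp
      }
      proj <- project_interval(blk, blk$a_chrom, a_int[1L], a_int[2L])
      if (is.null(proj)) next
      gain <- if (a_gain) list(blk$a_chrom, a_int[1L], a_int[2L]) else
        list(proj$chrom, proj$start, proj$end)
      loss <- if (a_gain) list(proj$chrom, proj$start, proj$end) else
        list(blk$a_chrom, a_int[1L], a_int[2L])
      if (n_info_in(gain[[1L]], gain[[2L]], gain[[3L]]) <
            config$min_event_probes) next
      if (n_info_in(loss[[1L]], loss[[2L]], loss[[3L]]) <
            config$min_event_probes) next
      if (clash(gain[[1L]], gain[[2L]], gain[[3L]]) ||
            clash(loss[[1L]], loss[[2L]], loss[[3L]])) next
      apply_region(gain[[1L]], gain[[2L]], gain[[3L]], 2L)
      apply_region(loss[[1L]], loss[[2L]], loss[[3L]], 0L)
      add_event("her", gain = gain, loss = loss)
      return(invisible(TRUE))
    }
    invisible(FALSE)
  }
  segmental_event <- function(gain) {
    for (try in 1:20) {
      ci <- sample(nrow(cm), 1L)
      chrom <- cm$chromosome[ci]
      bp <- sort(stats::runif(2L, 1, cm$length[ci]))
      if (n_info_in(chrom, bp[1L], bp[2L]) < config$min_event_probes) next
      if (clash(chrom, bp[1L], bp[2L])) next
      apply_region(chrom, bp[1L], bp[2L], if (gain) 2L else 0L)
      if (gain) add_event("duplication", gain = list(chrom, bp[1L], bp[2L]))
      else add_event("deletion", loss = list(chrom, bp[1L], bp[2L]))
      return(invisible(TRUE))
    }
    invisible(FALSE)
  }
  aneuploid_event <- function(gain) {
    for (try in 1:20) {
      ci <- sample(nrow(cm), 1L)
      chrom <- cm$chromosome[ci]
      if (clash(chrom, 1, cm$length[ci])) next
      apply_region(chrom, 1, cm$length[ci], if (gain) 2L else 0L)
      if (gain) {
        add_event("aneuploid_gain", gain = list(chrom, 1, cm$length[ci]))
      } else {
        add_event("aneuploid_loss", loss = list(chrom, 1, cm$length[ci]))
      }
      return(invisible(TRUE))
    }
    invisible(FALSE)
  }

  if (occurs[["her_terminal"]]) her_event(terminal = TRUE)
  if (occurs[["her_interstitial"]]) her_event(terminal = FALSE)
  if (occurs[["deletion"]]) segmental_event(gain = FALSE)
  if (occurs[["duplication"]]) segmental_event(gain = TRUE)
  if (occurs[["aneuploid_gain"]]) aneuploid_event(gain = TRUE)
  if (occurs[["aneuploid_loss"]]) aneuploid_event(gain = FALSE)

  ev <- if (length(events)) data.table::rbindlist(events) else NULL
  list(dose = dose, events = ev, regions = occupied)
}

#' Simulate a full testcross population with truth catalogue
#'
#' Marker status (monomorphic / null-parent / polymorphic with random
#' parental allele orientation) is drawn once for the cross; each progeny
#' combines one simulated gamete from each parent; genotypes are rendered as
#' theta/R intensities with [render_intensities()].
#'
#' @param config A [sim_config()].
#' @return A list: `intensities` (long table incl. the parents
#'   `"P1"`/`"P2"`), `truth` (planted event catalogue with `individual_id`,
#'   `n_support` = min informative loci over regions), `truth_genotypes`
#'   (markers x progeny matrix of generating states), `marker_status`
#'   (per-probe: `status`, `aa_parent`, `informative`), `marker_map`,
#'   `parents = c("P1", "P2")`, `config`.
#' @export
simulate_population <- function(config) {
  probes <- config$marker_map$probes
  n_mark <- nrow(probes)
  set.seed(derive_seed(config$seed, "markers"))
  u <- stats::runif(n_mark)
  status <- data.table::fifelse(
    u < config$fraction_monomorphic, "monomorphic",
    data.table::fifelse(
      u < config$fraction_monomorphic + config$null_marker_rate,
      "null_parent", "polymorphic"))
  aa_parent <- data.table::fifelse(
    status == "polymorphic",
    1L + (stats::runif(n_mark) < 0.5), NA_integer_)
  null_parent <- data.table::fifelse(
    status == "null_parent", 1L + (stats::runif(n_mark) < 0.5), NA_integer_)
  mono_allele <- data.table::fifelse(stats::runif(n_mark) < 0.5, "AA", "BB")
  informative <- status == "polymorphic"
  marker_status <- data.table::data.table(
    probe_id = probes$probe_id, status = status, aa_parent = aa_parent,
    null_parent = null_parent, informative = informative)

  truth <- list()
  geno <- vector("list", config$n_individuals)
  for (i in seq_len(config$n_individuals)) {
    ind <- sprintf("F1_%03d", i)
    g1 <- simulate_meiosis("parent1", config, informative,
                           seed = derive_seed(config$seed, "meiosis", i, 1))
    g2 <- simulate_meiosis("parent2", config, informative,
                           seed = derive_seed(config$seed, "meiosis", i, 2),
                           occupied = g1$regions)
    for (ev in list(g1$events, g2$events)) {
      if (!is.null(ev)) {
        ev <- data.table::copy(ev)
        ev[, individual_id := ind]
        truth[[length(truth) + 1L]] <- ev
      }
    }
    geno[[i]] <- genotype_from_doses(g1$dose, g2$dose, marker_status)
  }
  truth <- if (length(truth)) data.table::rbindlist(truth) else
    data.table::data.table()
  if (nrow(truth)) {
    truth[, n_support := pmin(data.table::fcoalesce(n_support_gain, 99999L),
                              data.table::fcoalesce(n_support_loss, 99999L))]
  }
  geno_mat <- do.call(cbind, geno)
  colnames(geno_mat) <- sprintf("F1_%03d", seq_len(config$n_individuals))
  rownames(geno_mat) <- probes$probe_id
  intensities <- render_intensities(geno_mat, marker_status, probes, config)
  list(intensities = intensities, truth = truth,
       truth_genotypes = geno_mat,
       marker_status = marker_status, marker_map = config$marker_map,
       parents = c("P1", "P2"), config = config)
}

## internal: progeny genotype state per marker from the two gamete doses
genotype_from_doses <- function(d1, d2, marker_status) {
  st <- marker_status
  n <- nrow(st)
  g <- character(n)
  poly <- st$status == "polymorphic"
  ## copies of the low-theta A allele and the B allele
  na <- ifelse(st$aa_parent == 1L, d1, d2)
  nb <- ifelse(st$aa_parent == 1L, d2, d1)
  key <- paste0(na, nb)
  map <- c("11" = "AB", "10" = "A0", "01" = "B0", "21" = "AAB",
           "12" = "ABB", "00" = "null", "20" = "AA", "02" = "BB",
           "22" = "AB")
  g[poly] <- map[key[poly]]
  g[poly & (is.na(g) | g == "")] <- "AB"
  mono <- st$status == "monomorphic"
  g[mono] <- "AA"
  np <- st$status == "null_parent"
  ## progeny carry only the amplifying parent's allele; orient it A or B by
  ## the marker's stored null parent (parent1 null -> allele from parent2)
  g[np] <- ifelse(st$null_parent[np] == 1L, "B0", "A0")
  g
}

#' Render genotype states as theta/R intensity records
#'
#' theta is the state's cluster centre plus Gaussian noise truncated to
#' \[0, 1\]; R is the state's amplification level (full for two-allele
#' states, elevated for three-dose, reduced for hemizygous, near zero for
#' null) under multiplicative lognormal noise.  Progeny records are dropped
#' at the no-call rate; parents (`P1`, `P2`) are always rendered complete.
#'
#' @param geno_mat Character matrix (markers x progeny) of states.
#' @param marker_status Marker status table from [simulate_population()].
#' @param probes Probe table (`probe_id`, `chromosome`, `position`).
#' @param config A [sim_config()].
#' @return Long-format intensity `data.table`.
#' @export
render_intensities <- function(geno_mat, marker_status, probes, config) {
  set.seed(derive_seed(config$seed, "render"))
  centers <- config$theta_centers
  r_level <- c(AA = 1, AB = 1, BB = 1, AAB = 1.2, ABB = 1.2,
               A0 = config$hemizygote_r_fraction,
               B0 = config$hemizygote_r_fraction,
               null = config$r_null)
  st <- marker_status
  ## parent states per marker
  p_state <- function(which_parent) {
    out <- rep("AA", nrow(st))
    poly <- st$status == "polymorphic"
    out[poly] <- ifelse(st$aa_parent[poly] == which_parent, "AA", "BB")
    np <- st$status == "null_parent"
    out[np] <- ifelse(st$null_parent[np] == which_parent, "null",
                      ifelse(st$null_parent[np] == 1L, "BB", "AA"))
    out
  }
  render_one <- function(states, individual) {
    th <- centers[states] +
      stats::rnorm(length(states), 0, config$theta_noise_sd)
    th[states == "null"] <- stats::runif(sum(states == "null"), 0, 1)
    th <- pmin(pmax(th, 0), 1)
    r <- r_level[states] *
      exp(stats::rnorm(length(states), 0, config$r_noise_sd))
    data.table::data.table(individual_id = individual,
                           probe_id = st$probe_id, theta = th, r = r)
  }
  recs <- vector("list", ncol(geno_mat) + 2L)
  recs[[1L]] <- render_one(p_state(1L), "P1")
  recs[[2L]] <- render_one(p_state(2L), "P2")
  for (j in seq_len(ncol(geno_mat))) {
    one <- render_one(geno_mat[, j], colnames(geno_mat)[j])
    if (config$nc_rate > 0) {
      keep <- stats::runif(nrow(one)) >= config$nc_rate
      one <- one[keep]
    }
    recs[[j + 2L]] <- one
  }
  data.table::rbindlist(recs)
}

#' Simulate a windowed read-depth profile with planted fixed events
#'
#' Windows tile each chromosome at `window_size`; each window's raw depth is
#' `depth_mean` times its copy ratio under multiplicative lognormal noise.
#' Fixed events are given as copy-ratio intervals and are planted
#' reciprocally by the caller (a homoeologous gain/loss pair is two rows).
#'
#' @param chrom_models Chromosome model table.
#' @param fixed_events `data.table` with `chromosome`, `start`, `end`,
#'   `copy_ratio` (e.g. 1.5 gain, 0.5 loss); may be empty.
#' @param window_size Window width in bp (default 1e5).
#' @param depth_mean Mean euploid depth (default 30).
#' @param noise_sd Multiplicative noise SD (default from `seed`less 0.05).
#' @param seed Integer seed.
#' @return A `data.table` of depth windows (`chromosome`, `start`, `end`,
#'   `raw_depth`).
#' @export
simulate_depth <- function(chrom_models, fixed_events = NULL,
                           window_size = 1e5, depth_mean = 30,
                           noise_sd = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cm <- data.table::as.data.table(chrom_models)
  win <- cm[, {
    s <- seq(1, length, by = window_size)
    .(start = s, end = pmin(s + window_size - 1, length))
  }, by = chromosome]
  win[, raw_depth := depth_mean]
  if (!is.null(fixed_events) && nrow(fixed_events)) {
    for (i in seq_len(nrow(fixed_events))) {
      fe <- fixed_events[i]
      sel <- win$chromosome == fe$chromosome & win$start <= fe$end &
        win$end >= fe$start
      win$raw_depth[sel] <- win$raw_depth[sel] * fe$copy_ratio
    }
  }
  win[, raw_depth := raw_depth * exp(stats::rnorm(.N, 0, noise_sd))]
  win[]
}
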