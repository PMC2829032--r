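#' Configuration for a synthetic densitometry cohort
#'
#' Describes the two-population structure of a Western-blot densitometry
#' experiment: an unstressed control group and a stressed group, each
#' characterised by the mean and standard deviation of the proBDNF percentage
#' of total BDNF. Defaults encode the structure reported for seabass: control
#' brain pro-fraction centred at 40% with SD 3 (so mean + 1SD = 43), stressed
#' brain elevated well above that threshold, and liver showing no stress
#' effect around 42%.
#'
#' Band intensities are modelled as a shared per-lane loading factor
#' (log-normal, coefficient of variation `lane_noise_cv`) multiplying the
#' true signal; the loading-control (alpha-tubulin) band carries the same
#' factor, so normalisation cancels it exactly.
#'
#' @param tissue `"brain"` or `"liver"`; selects the default population
#'   parameters.
#' @param n_control,n_stressed Number of animals per group (default 15 each).
#' @param control_mean_profrac,control_sd_profrac Mean and SD (percentage
#'   points) of the control pro-fraction.
#' @param stressed_mean_profrac,stressed_sd_profrac Mean and SD of the
#'   stressed pro-fraction.
#' @param intensity_scale Total BDNF band intensity per lane, in arbitrary
#'   densitometry units.
#' @param lane_noise_cv Coefficient of variation of the multiplicative
#'   per-lane loading factor.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A list of class `cohort_config`.
#' @seealso [generate_densitometry_cohort()]
#' @export
#' @examples
#' cohort_config("brain")
#' cohort_config("liver", n_control = 10, n_stressed = 10)
cohort_config <- function(tissue = c("brain", "liver"),
                          n_control = 15,
                          n_stressed = 15,
                          control_mean_profrac = NULL,
                          control_sd_profrac = NULL,
                          stressed_mean_profrac = NULL,
                          stressed_sd_profrac = NULL,
                          intensity_scale = 1000,
                          lane_noise_cv = 0.2,
                          seed = 1L) {
  tissue <- match.arg(tissue)
  defaults <- if (tissue == "brain") {
    list(cm = 40, cs = 3, sm = 52, ss = 2.5)
  } else {
    list(cm = 42, cs = 4, sm = 42, ss = 4)
  }
  cfg <- list(
    tissue = tissue,
    n_control = assert_count(n_control, "n_control"),
    n_stressed = assert_count(n_stressed, "n_stressed"),
    control_mean_profrac = control_mean_profrac %||% defaults$cm,
    control_sd_profrac = control_sd_profrac %||% defaults$cs,
    stressed_mean_profrac = stressed_mean_profrac %||% defaults$sm,
    stressed_sd_profrac = stressed_sd_profrac %||% defaults$ss,
    intensity_scale = intensity_scale,
    lane_noise_cv = lane_noise_cv,
    seed = as.integer(seed)
  )
  assert_scalar_number(cfg$control_mean_profrac, "control_mean_profrac",
                       0, 100, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(cfg$stressed_mean_profrac, "stressed_mean_profrac",
                       0, 100, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(cfg$control_sd_profrac, "control_sd_profrac",
                       0, Inf, strict_lower = TRUE)
  assert_scalar_number(cfg$stressed_sd_profrac, "stressed_sd_profrac",
                       0, Inf, strict_lower = TRUE)
  assert_scalar_number(cfg$intensity_scale, "intensity_scale",
                       0, Inf, strict_lower = TRUE)
  assert_scalar_number(cfg$lane_noise_cv, "lane_noise_cv", 0, 1)
  structure(cfg, class = "cohort_config")
}

# Normal truncated to (0.5, 99.5) by rejection; keeps the reporting scale of
# a percentage while ruling out degenerate 0/100 lanes.
rtrunc_profrac <- function(n, mean, sd) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > 0.5 & draw < 99.5
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Log-normal with expectation 1 and coefficient of variation cv.
rlane_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate a synthetic densitometry cohort
#'
#' Draws one pro-fraction per animal from its group's truncated-normal
#' distribution and converts it into raw band intensities: a shared
#' log-normal lane factor multiplies total BDNF (split between the proBDNF
#' and matBDNF bands according to the drawn fraction) and the alpha-tubulin
#' loading control. Because all three bands in a lane share the factor, the
#' pro-fraction is recoverable exactly from the raw bands and is invariant
#' under tubulin normalisation.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per animal and columns `animal_id`, `group`
#'   (`"control"`/`"stressed"`), `tissue`, `band_pro`, `band_mat`,
#'   `band_tubulin`, `seed`. The latent drawn fractions are attached as
#'   attribute `"latent_profrac"`.
#' @export
#' @examples
#' cohort <- generate_densitometry_cohort(cohort_config("brain", seed = 42))
#' head(cohort)
generate_densitometry_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().",
          class = "probdnf_config_error")
  }
  n <- config$n_control + config$n_stressed
  with_seed(config$seed, {
    frac <- c(
      rtrunc_profrac(config$n_control, config$control_mean_profrac,
                     config$control_sd_profrac),
      rtrunc_profrac(config$n_stressed, config$stressed_mean_profrac,
                     config$stressed_sd_profrac)
    )
    lane <- rlane_factor(n, config$lane_noise_cv)
    total <- lane * config$intensity_scale
    out <- tibble(
      animal_id = sprintf("%s_%s_%02d", substr(config$tissue, 1, 1),
                          rep(c("ctl", "str"),
                              c(config$n_control, config$n_stressed)),
                          c(seq_len(config$n_control),
                            seq_len(config$n_stressed))),
      group = rep(c("control", "stressed"),
                  c(config$n_control, config$n_stressed)),
      tissue = config$tissue,
      band_pro = total * frac / 100,
      band_mat = total * (1 - frac / 100),
      band_tubulin = lane * config$intensity_scale,
      seed = config$seed
    )
    attr(out, "latent_profrac") <- frac
    out
  })
}

#' Configuration for a synthetic semiquantitative RT-PCR panel
#'
#' Describes per-variant expression of the bipartite BDNF transcripts in
#' control and stressed animals. Each measurement is a variant band and a
#' beta-actin band sharing a multiplicative lane factor; the stressed group's
#' expected normalised expression is the control mean times the variant's
#' `stressed_multiplier`. The default multipliers encode down-regulation of
#' variants 1c and 1d (x0.6) with the remaining variants unchanged.
#'
#' @param variants Character vector of transcript-variant labels.
#' @param n_per_group Replicates per group per variant (default 5).
#' @param control_mean Expected normalised expression in controls.
#' @param stressed_multiplier Named numeric vector of per-variant fold
#'   changes; names must be a subset of `variants`, unnamed variants get 1.
#' @param noise_cv Coefficient of variation of the biological (log-normal)
#'   noise on expression.
#' @param seed Integer seed.
#' @return A list of class `expression_panel_config`.
#' @export
#' @examples
#' expression_panel_config()
#' expression_panel_config(stressed_multiplier = c("1c" = 0.5))
expression_panel_config <- function(variants = c("1beta", "1a", "1b", "1c", "1d", "2"),
                                    n_per_group = 5,
                                    control_mean = 1,
                                    stressed_multiplier = c("1c" = 0.6, "1d" = 0.6),
                                    noise_cv = 0.15,
                                    seed = 1L) {
  if (!is.character(variants) || anyDuplicated(variants) || length(variants) < 1) {
    abort("`variants` must be distinct non-empty labels.",
          class = "probdnf_config_error")
  }
  bad <- setdiff(names(stressed_multiplier), variants)
  if (length(bad) > 0) {
    abort(paste0("Unknown variant label(s) in `stressed_multiplier`: ",
                 paste(bad, collapse = ", ")),
          class = "probdnf_config_error")
  }
  mult <- setNames(rep(1, length(variants)), variants)
  mult[names(stressed_multiplier)] <- stressed_multiplier
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    abort("All stressed multipliers must be positive.",
          class = "probdnf_config_error")
  }
  cfg <- list(
    variants = variants,
    n_per_group = assert_count(n_per_group, "n_per_group", min = 2),
    control_mean = assert_scalar_number(control_mean, "control_mean",
                                        0, Inf, strict_lower = TRUE),
    stressed_multiplier = mult,
    noise_cv = assert_scalar_number(noise_cv, "noise_cv", 0, 1),
    seed = as.integer(seed)
  )
  structure(cfg, class = "expression_panel_config")
}

#' Generate a synthetic semiquantitative RT-PCR panel
#'
#' @param config An [expression_panel_config()].
#' @return A tibble with columns `variant`, `group`, `replicate`,
#'   `band_variant`, `band_actin`; one row per variant x group x replicate.
#' @export
#' @examples
#' panel <- generate_expression_panel(expression_panel_config(seed = 7))
#' dplyr::count(panel, variant, group)
generate_expression_panel <- function(config = expression_panel_config()) {
  if (!inherits(config, "expression_panel_config")) {
    abort("`config` must be created by expression_panel_config().",
          class = "probdnf_config_error")
  }
  grid <- tidyr::expand_grid(
    variant = config$variants,
    group = c("control", "stressed"),
    replicate = seq_len(config$n_per_group)
  )
  with_seed(config$seed, {
    nr <- nrow(grid)
    mean_expr <- config$control_mean *
      if_else(grid$group == "stressed",
              unname(config$stressed_multiplier[grid$variant]), 1)
    expr <- mean_expr * rlane_factor(nr, config$noise_cv)
    lane <- rlane_factor(nr, 0.2)  # template-amount variation, cancelled by actin
    mutate(grid,
           band_variant = lane * expr,
           band_actin = lane)
  })
}

#' Blueprint for a synthetic test locus
#'
#' Specifies exons (1-based inclusive coordinates on the plus strand),
#' motifs to plant at known positions, and a seed for the random intron and
#' flank fill. Introns are synthesised with canonical GT...AG boundaries so
#' the locus validates by construction; planted motifs are recorded in an
#' answer key so scanner output can be checked round-trip.
#'
#' @param exons A data frame with columns `name`, `start`, `end`; exons must
#'   be non-overlapping and strictly ordered, with at least 4 nt between
#'   consecutive exons to fit a GT...AG intron.
#' @param motifs Optional data frame with columns `seq`, `position` (1-based
#'   genomic start) of motifs to plant outside exon-boundary dinucleotides.
#' @param flank Extra random sequence appended after the last exon.
#' @param seed Integer seed.
#' @return A list of class `locus_blueprint`.
#' @export
locus_blueprint <- function(exons, motifs = NULL, flank = 50, seed = 1L) {
  exons <- as_tibble(exons)
  stopifnot(all(c("name", "start", "end") %in% names(exons)))
  if (nrow(exons) < 1 || anyDuplicated(exons$name)) {
    abort("`exons` must have at least one row with unique names.",
          class = "probdnf_blueprint_error")
  }
  if (any(exons$start > exons$end) || any(exons$start < 1)) {
    abort("Exon coordinates must satisfy 1 <= start <= end.",
          class = "probdnf_blueprint_error")
  }
  o <- order(exons$start)
  if (!identical(o, seq_len(nrow(exons)))) {
    abort("Exons must be given in increasing coordinate order.",
          class = "probdnf_blueprint_error")
  }
  if (nrow(exons) > 1) {
    gap <- exons$start[-1] - exons$end[-nrow(exons)] - 1
    if (any(gap < 4)) {
      abort("Exons overlap or leave no room for a GT...AG intron (need gap >= 4).",
            class = "probdnf_blueprint_error")
    }
  }
  if (!is.null(motifs)) {
    motifs <- as_tibble(motifs)
    stopifnot(all(c("seq", "position") %in% names(motifs)))
    motifs$seq <- vapply(motifs$seq, clean_dna, character(1), name = "motif")
  }
  structure(list(exons = exons, motifs = motifs,
                 flank = assert_count(flank, "flank", min = 0),
                 seed = as.integer(seed)),
            class = "locus_blueprint")
}

#' Generate a synthetic genomic locus with a known answer key
#'
#' Builds a random genomic sequence around the blueprint's exons, writing the
#' canonical splice dinucleotides (GT immediately after every non-terminal
#' exon, AG immediately before every non-initial exon) and planting the
#' requested motifs. Accidental exact copies of the canonical CRE octamer
#' (`TGACGTCA`) arising in random fill are mutated away so that exact-match
#' motif scans recover the answer key exactly.
#'
#' @param blueprint A [locus_blueprint()].
#' @return A list of class `bdnf_locus` with elements `sequence` (character),
#'   `model` (a [gene_model()] over the blueprint exons), and `key` (list of
#'   planted motif positions and exon coordinates).
#' @export
#' @examples
#' bp <- locus_blueprint(
#'   exons = data.frame(name = c("1c", "2"), start = c(101, 301),
#'                      end = c(200, 400)),
#'   motifs = data.frame(seq = "TGACGTCA", position = 21),
#'   seed = 5
#' )
#' locus <- generate_test_locus(bp)
#' validate_splice_junctions(locus$sequence, locus$model)
generate_test_locus <- function(blueprint) {
  if (!inherits(blueprint, "locus_blueprint")) {
    abort("`blueprint` must be created by locus_blueprint().",
          class = "probdnf_blueprint_error")
  }
  ex <- blueprint$exons
  total_len <- max(ex$end) + blueprint$flank
  with_seed(blueprint$seed, {
    chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)

    protected <- integer(0)
    n_ex <- nrow(ex)
    for (i in seq_len(n_ex)) {
      if (i < n_ex) {  # donor GT after exon end
        chars[ex$end[i] + 1] <- "G"
        chars[ex$end[i] + 2] <- "T"
        protected <- c(protected, ex$end[i] + 1:2)
      }
      if (i > 1) {     # acceptor AG before exon start
        chars[ex$start[i] - 2] <- "A"
        chars[ex$start[i] - 1] <- "G"
        protected <- c(protected, ex$start[i] - 2:1)
      }
    }

    planted <- integer(0)
    if (!is.null(blueprint$motifs)) {
      for (j in seq_len(nrow(blueprint$motifs))) {
        m <- blueprint$motifs$seq[j]
        p <- blueprint$motifs$position[j]
        idx <- p:(p + nchar(m) - 1)
        if (max(idx) > total_len || min(idx) < 1) {
          abort("Planted motif falls outside the generated sequence.",
                class = "probdnf_blueprint_error")
        }
        chars[idx] <- strsplit(m, "")[[1]]
        protected <- c(protected, idx)
        planted <- c(planted, p)
      }
    }

    # Scrub accidental exact CRE octamers so exact scans match the key.
    seq_str <- paste(chars, collapse = "")
    cre <- "TGACGTCA"
    for (iter in 1:10) {
      hits <- gregexpr(cre, seq_str, fixed = TRUE)[[1]]
      hits <- hits[hits > 0 & !(hits %in% planted)]
      if (length(hits) == 0) break
      for (h in hits) {
        idx <- h:(h + 7)
        free <- setdiff(idx, protected)
        if (length(free) == 0) next
        i <- free[[1]]
        cur <- substr(seq_str, i, i)
        substr(seq_str, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[1]
      }
    }

    model <- gene_model(ex, seqid = "synthetic_locus")
    key <- list(
      exons = ex,
      motifs = if (is.null(blueprint$motifs)) {
        tibble(seq = character(), position = integer())
      } else {
        blueprint$motifs
      }
    )
    structure(list(sequence = seq_str, model = model, key = key),
              class = "bdnf_locus")
  })
}

#' Read or write a densitometry cohort as TSV
#'
#' The on-disk schema is `animal_id  group  tissue  band_pro  band_mat
#' band_tubulin  seed`.
#'
#' @param cohort A cohort tibble from [generate_densitometry_cohort()] or of
#'   the same shape.
#' @param path File path.
#' @return `write_cohort_tsv()` returns `cohort` invisibly;
#'   `read_cohort_tsv()` returns the cohort tibble.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(cohort)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    animal_id = "c", group = "c", tissue = "c",
                    band_pro = "d", band_mat = "d", band_tubulin = "d"
                  ))
}

#' Write a synthetic locus to FASTA plus a JSON answer key
#'
#' @param locus A `bdnf_locus` from [generate_test_locus()].
#' @param fasta_path,key_path Output paths; the FASTA is wrapped at 60
#'   columns.
#' @return `locus`, invisibly.
#' @export
write_locus <- function(locus, fasta_path, key_path) {
  stopifnot(inherits(locus, "bdnf_locus"))
  dna <- Biostrings::DNAStringSet(setNames(locus$sequence, "synthetic_locus"))
  Biostrings::writeXStringSet(dna, fasta_path, width = 60)
  jsonlite::write_json(locus$key, key_path, auto_unbox = TRUE, digits = NA)
  invisible(locus)
}
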