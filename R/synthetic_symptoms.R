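# Synthetic symptom-table generator: per-subject demographic and ADI-R
# domain-score records with configurable between-sex effect sizes, site
# shifts, and deterministic per-subject RNG substreams.

.DOMAINS <- c("adi_social", "adi_comm", "adi_rrb")

# score scales: conventional ADI-R diagnostic-algorithm ranges; means/SDs
# per diagnostic group (TD children score near the floor on a parent
# interview probing autism symptoms)
.SCORE_SCALE <- list(
  adi_social = list(mean = c(ASD = 20, TD = 2),  sd = 6,   range = c(0, 30)),
  adi_comm   = list(mean = c(ASD = 16, TD = 2),  sd = 5,   range = c(0, 26)),
  adi_rrb    = list(mean = c(ASD = 6,  TD = 0.5), sd = 2.5, range = c(0, 12))
)

.subject_seed <- function(seed, idx, stream = 0L) {
  as.integer((as.double(seed) * 48271 + stream * 7919 + idx) %% 2147483647)
}

#' Specify a synthetic cohort
#'
#' Defines the design of a synthetic cohort: cell sizes of the
#' group-by-sex layout, standardized between-sex score differences per
#' ADI-R domain, demographic ranges, and site structure.
#'
#' @param n_per_cell named integer vector of subjects per `group.sex` cell
#'   (e.g. `c(ASD.F = 25, ASD.M = 25, TD.F = 19, TD.M = 19)`), or a single
#'   count used for all four cells. Each count must be at least 2.
#' @param domain_effects named numeric vector of standardized mean
#'   differences (Cohen's d, female minus male, applied within each
#'   diagnostic group) for any of `adi_social`, `adi_comm`, `adi_rrb`.
#' @param age_range numeric length-2, years; ages drawn uniformly.
#' @param iq_mean_sd numeric length-2: mean and SD of full-scale IQ.
#' @param n_sites number of acquisition sites; subjects are dealt to sites
#'   in rotation within each cell so every site contributes equally to
#'   every cell.
#' @param site_effect_sd SD (score units) of a per-site additive shift
#'   applied to all domain scores.
#' @param seed integer master seed; identical spec + seed reproduce the
#'   cohort exactly.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_symptom_cohort()], [generate_gm_cohort()],
#'   [ndar_cohort_spec()], [abide_cohort_spec()]
#' @export
cohort_spec <- function(n_per_cell,
                        domain_effects = c(adi_social = 0, adi_comm = 0, adi_rrb = 0),
                        age_range = c(7, 13),
                        iq_mean_sd = c(105, 15),
                        n_sites = 1,
                        site_effect_sd = 0,
                        seed = 1L) {
  if (length(n_per_cell) == 1 && is.null(names(n_per_cell)))
    n_per_cell <- c(ASD.F = n_per_cell, ASD.M = n_per_cell,
                    TD.F = n_per_cell, TD.M = n_per_cell)
  cells <- names(n_per_cell)
  if (is.null(cells) || !all(grepl("^(ASD|TD)\\.(F|M)$", cells)))
    stop("n_per_cell must be named with cells of the form 'ASD.F', 'TD.M', ...")
  if (any(n_per_cell < 2)) stop("all cell counts must be >= 2")
  if (!all(names(domain_effects) %in% .DOMAINS))
    stop("unknown domain name(s): ",
         paste(setdiff(names(domain_effects), .DOMAINS), collapse = ", "))
  if (any(!is.finite(domain_effects))) stop("domain_effects must be finite")
  if (age_range[1] >= age_range[2]) stop("age_range must satisfy min < max")
  if (n_sites < 1) stop("n_sites must be >= 1")
  d <- setNames(numeric(length(.DOMAINS)), .DOMAINS)
  d[names(domain_effects)] <- domain_effects
  structure(list(n_per_cell = n_per_cell, domain_effects = d,
                 age_range = as.numeric(age_range),
                 iq_mean_sd = as.numeric(iq_mean_sd),
                 n_sites = as.integer(n_sites),
                 site_effect_sd = as.numeric(site_effect_sd),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Preset cohort specs emulating the two study designs
#'
#' `ndar_cohort_spec()` emulates a large single-instrument symptom-only
#' cohort (128 ASD girls vs 614 ASD boys); `abide_cohort_spec()` emulates
#' a four-cell imaging cohort (25/25 ASD girls/boys, 19/19 TD girls/boys,
#' six sites). Default domain effects are the standardized differences
#' implied by the corresponding published t statistics and group sizes
#' (d = t * sqrt(1/n1 + 1/n2)); the dominant effect is a reduction of
#' repetitive/restricted behavior severity in girls.
#'
#' @param seed integer master seed.
#' @param domain_effects override the preset standardized differences.
#' @return a [cohort_spec()].
#' @export
ndar_cohort_spec <- function(seed = 1L,
                             domain_effects = c(adi_social = -0.106,
                                                adi_comm = -0.112,
                                                adi_rrb = -0.504)) {
  cohort_spec(n_per_cell = c(ASD.F = 128, ASD.M = 614),
              domain_effects = domain_effects, n_sites = 1,
              site_effect_sd = 0, seed = seed)
}

#' @rdname ndar_cohort_spec
#' @export
abide_cohort_spec <- function(seed = 1L,
                              domain_effects = c(adi_social = -0.207,
                                                 adi_comm = -0.161,
                                                 adi_rrb = -0.786)) {
  cohort_spec(n_per_cell = c(ASD.F = 25, ASD.M = 25, TD.F = 19, TD.M = 19),
              domain_effects = domain_effects, n_sites = 6,
              site_effect_sd = 0.5, seed = seed)
}

#' Generate a synthetic symptom table
#'
#' Draws one record per subject: group, sex, age, IQ, site, and the three
#' ADI-R domain scores plus their total. Scores are Gaussian in the latent
#' scale, shifted by half the requested standardized difference per sex
#' (+d/2 for girls, -d/2 for boys, within each diagnostic group) and by
#' the per-site shift, then rounded to integers and clipped to plausible
#' ADI-R ranges. Each subject has an RNG substream derived from
#' `(seed, subject index)`, so enlarging a cohort never reshuffles
#' existing subjects.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` (class `symptom_table`) with columns
#'   `subject_id, group, sex, age, iq, site, adi_social, adi_comm,
#'   adi_rrb, adi_total`.
#' @examples
#' tab <- generate_symptom_cohort(cohort_spec(c(ASD.F = 10, ASD.M = 10), seed = 1))
#' head(tab)
#' @export
generate_symptom_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cells <- names(spec$n_per_cell)
  # site shifts from a dedicated stream of the master seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.subject_seed(spec$seed, 0L, stream = 1L))
  site_shift <- rnorm(spec$n_sites, 0, spec$site_effect_sd)

  rows <- vector("list", sum(spec$n_per_cell))
  idx <- 0L
  for (cell in cells) {
    parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
    grp <- parts[1]; sex <- parts[2]
    for (k in seq_len(spec$n_per_cell[[cell]])) {
      idx <- idx + 1L
      site <- (k - 1L) %% spec$n_sites + 1L
      set.seed(.subject_seed(spec$seed, idx, stream = 0L))
      age <- runif(1, spec$age_range[1], spec$age_range[2])
      iq <- rnorm(1, spec$iq_mean_sd[1], spec$iq_mean_sd[2])
      sc <- numeric(3)
      for (j in seq_along(.DOMAINS)) {
        dom <- .DOMAINS[j]
        sl <- .SCORE_SCALE[[dom]]
        dshift <- spec$domain_effects[[dom]] * sl$sd * (if (sex == "F") 0.5 else -0.5)
        mu <- sl$mean[[grp]] + dshift + site_shift[site]
        x <- round(rnorm(1, mu, sl$sd))
        sc[j] <- min(max(x, sl$range[1]), sl$range[2])
      }
      rows[[idx]] <- data.frame(
        subject_id = sprintf("S%04d", idx), group = grp, sex = sex,
        age = age, iq = iq, site = sprintf("site%02d", site),
        adi_social = sc[1], adi_comm = sc[2], adi_rrb = sc[3],
        adi_total = sum(sc), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = c("ASD", "TD")[c("ASD", "TD") %in% out$group])
  out$sex <- factor(out$sex, levels = c("F", "M"))
  out$site <- factor(out$site)
  class(out) <- c("symptom_table", "data.frame")
  attr(out, "spec") <- spec
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Read/write symptom tables as tab-separated files
#'
#' The on-disk format is TSV with the canonical header
#' `subject_id group sex age iq site adi_social adi_comm adi_rrb adi_total`.
#'
#' @param table a `symptom_table` data frame.
#' @param path file path.
#' @return `read_symptom_table` returns a `symptom_table`;
#'   `write_symptom_table` returns `path` invisibly.
#' @export
write_symptom_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_symptom_table
#' @export
read_symptom_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "sex", "age", "iq", "site", .DOMAINS)
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("symptom table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(out$subject_id)) stop("duplicate subject_id values")
  out$group <- factor(out$group)
  out$sex <- factor(out$sex, levels = intersect(c("F", "M"), unique(out$sex)))
  out$site <- factor(out$site)
  class(out) <- c("symptom_table", "data.frame")
  out
}
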