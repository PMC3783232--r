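# Pathway classification from embryo ploidy and peak index, and the
# decomposition of embryo/endosperm ploidies into female and male genomic
# contributions.

#' Classification thresholds for pathway calling
#'
#' @param pi_boundary Peak-index split between sexually derived (index below
#'   the boundary) and parthenogenetic (at or above) embryos. Default 2:
#'   a reduced egg fertilized by one sperm gives an index below 2, while a
#'   parthenogenetic embryo with pseudogamous endosperm gives at least 2.
#' @param maternal_match_tol Relative tolerance for "embryo recovers the
#'   maternal ploidy" (default 0.12, half the relative spacing of adjacent
#'   cytotypes at tetraploid level).
#' @param doubled_match_tol Relative tolerance for the doubled-embryo-sac
#'   match (embryo at twice the maternal ploidy; default 0.12).
#' @param near_boundary_band Peak-index half-width around `pi_boundary`
#'   within which calls carry a `near_boundary` flag (default 0.1).
#' @return A list of class `fcss_thresholds`.
#' @export
classification_thresholds <- function(pi_boundary = 2,
                                      maternal_match_tol = 0.12,
                                      doubled_match_tol = 0.12,
                                      near_boundary_band = 0.1) {
  stopifnot(pi_boundary > 1, maternal_match_tol > 0, doubled_match_tol > 0,
            near_boundary_band >= 0)
  structure(list(pi_boundary = pi_boundary,
                 maternal_match_tol = maternal_match_tol,
                 doubled_match_tol = doubled_match_tol,
                 near_boundary_band = near_boundary_band),
            class = "fcss_thresholds")
}

#' Classify the developmental pathway of a seed
#'
#' Applies the peak-index rule: indices below the boundary indicate a
#' sexually derived embryo (fertilization of the egg cell), indices at or
#' above it combined with recovery of the maternal ploidy by the embryo
#' indicate apomixis. An embryo at twice the maternal ploidy is an apomictic
#' seed from a doubled embryo sac (`Z_DOUBLED`); an embryo exceeding the
#' maternal ploidy with a low peak index comes from fertilization of an
#' unreduced egg cell (`L_UNREDUCED_EGG`). Seeds without a distinct
#' endosperm signal are `UNKNOWN`; seeds without any signal are `FAILED`.
#' Ambiguous combinations are labelled `UNKNOWN` with an `unclassifiable`
#' flag, never guessed.
#'
#' @param embryo_x Embryo ploidy in chromosome sets (may be `NA`: failed).
#' @param peak_index Endosperm/embryo peak index (may be `NA`: no endosperm
#'   signal).
#' @param maternal_x Maternal ploidy (chromosome sets, at least 2).
#' @param th [classification_thresholds()].
#' @return A tibble with columns `pathway` (character) and `flag`
#'   (`""`, `"unclassifiable"`, and/or `"near_boundary"`).
#' @export
classify_pathway <- function(embryo_x, peak_index, maternal_x,
                             th = classification_thresholds()) {
  stopifnot(inherits(th, "fcss_thresholds"))
  n <- max(length(embryo_x), length(peak_index), length(maternal_x))
  embryo_x <- rep_len(as.numeric(embryo_x), n)
  peak_index <- rep_len(as.numeric(peak_index), n)
  maternal_x <- rep_len(as.numeric(maternal_x), n)
  if (any(maternal_x < 2, na.rm = TRUE)) abort("maternal_x must be >= 2")
  if (any(embryo_x <= 0, na.rm = TRUE)) abort("embryo_x must be positive")

  rel <- function(a, b) abs(a - b) / b
  matches_m <- rel(embryo_x, maternal_x) <= th$maternal_match_tol
  matches_2m <- rel(embryo_x, 2 * maternal_x) <= th$doubled_match_tol
  low_pi <- peak_index < th$pi_boundary
  exceeds <- embryo_x > maternal_x * (1 + th$maternal_match_tol)

  pathway <- dplyr::case_when(
    is.na(embryo_x) ~ "FAILED",
    is.na(peak_index) ~ "UNKNOWN",
    matches_2m ~ "Z_DOUBLED",
    low_pi & matches_m ~ "SEXUAL",
    low_pi & exceeds ~ "L_UNREDUCED_EGG",
    !low_pi & matches_m ~ "APOMICTIC",
    TRUE ~ "UNKNOWN")
  flag <- dplyr::case_when(
    !is.na(embryo_x) & !is.na(peak_index) & pathway == "UNKNOWN" ~ "unclassifiable",
    TRUE ~ "")
  near <- !is.na(peak_index) &
    abs(peak_index - th$pi_boundary) <= th$near_boundary_band
  flag <- ifelse(near, paste0(flag, ifelse(flag == "", "", ";"), "near_boundary"),
                 flag)
  tibble::tibble(pathway = pathway, flag = flag)
}

#' Female and male genomic contributions to embryo and endosperm
#'
#' Decomposes the measured embryo and endosperm ploidies into female (f) and
#' male (m) chromosome-set contributions. The female contribution to the
#' embryo and endosperm is once and twice the embryo-sac ploidy (two polar
#' nuclei in the central cell); the male contribution is carried by the two
#' sperm of the pollen tube — one to the egg and one to the central cell in
#' sexually derived seeds, one or two to the central cell in seeds with
#' parthenogenetic embryos.
#'
#' Pathway-specific algebra (equal genome number per sperm assumed where two
#' sperm act):
#' \describe{
#'   \item{SEXUAL}{`f = endosperm_x - embryo_x`, `m_embryo = embryo_x - f`,
#'     `f_endosperm = 2 f`, `m_endosperm = endosperm_x - 2 f`.}
#'   \item{APOMICTIC / Z_DOUBLED}{parthenogenesis: `f = embryo_x`,
#'     `f_endosperm = 2 embryo_x`, `m_embryo = 0`,
#'     `m_endosperm = endosperm_x - 2 embryo_x`.}
#'   \item{L_UNREDUCED_EGG}{unreduced egg: `f = maternal_x`,
#'     `m_embryo = embryo_x - maternal_x`, `f_endosperm = 2 maternal_x`,
#'     `m_endosperm = endosperm_x - 2 maternal_x`.}
#' }
#' With `single_sperm_sexual = TRUE` the alternative decomposition in which
#' only one sperm reaches the central cell of sexually derived seeds is used
#' for sensitivity analysis; the embryo algebra is unchanged, and the
#' endosperm male dosage is read directly as `endosperm_x - 2 f`.
#'
#' Negative components more negative than -0.25 chromosome sets violate the
#' pathway's dosage identities and raise an error naming the offending
#' entries; small negatives (measurement noise) are clipped to zero and
#' flagged.
#'
#' @param embryo_x,endosperm_x Measured ploidies (chromosome sets).
#' @param maternal_x Maternal ploidy.
#' @param pathway Pathway label per [classify_pathway()]; only the four
#'   classified pathways are decomposable.
#' @param single_sperm_sexual Logical; see Details.
#' @param seed_id Optional identifiers used in error messages.
#' @param on_inconsistent `"error"` (default) raises on a dosage-identity
#'   violation; `"flag"` instead returns `NA` components with the
#'   `inconsistent` column set, so that batch callers can keep such seeds
#'   labelled rather than abort a whole run.
#' @return A tibble: `f_embryo_x`, `m_embryo_x`, `f_endosperm_x`,
#'   `m_endosperm_x`, `clipped`, `inconsistent` (logicals).
#' @export
genomic_contributions <- function(embryo_x, endosperm_x, maternal_x, pathway,
                                  single_sperm_sexual = FALSE,
                                  seed_id = NULL,
                                  on_inconsistent = c("error", "flag")) {
  on_inconsistent <- match.arg(on_inconsistent)
  n <- max(length(embryo_x), length(endosperm_x), length(maternal_x),
           length(pathway))
  embryo_x <- rep_len(as.numeric(embryo_x), n)
  endosperm_x <- rep_len(as.numeric(endosperm_x), n)
  maternal_x <- rep_len(as.numeric(maternal_x), n)
  pathway <- rep_len(as.character(pathway), n)
  if (is.null(seed_id)) seed_id <- as.character(seq_len(n))
  bad_path <- !pathway %in% c("SEXUAL", "APOMICTIC", "Z_DOUBLED", "L_UNREDUCED_EGG")
  if (any(bad_path))
    abort(paste0("pathway not decomposable for: ",
                 paste(seed_id[bad_path], collapse = ", ")))
  if (any(is.na(endosperm_x)))
    abort("endosperm_x must be present for contribution decomposition")

  f_emb <- m_emb <- f_end <- m_end <- rep(NA_real_, n)
  sex <- pathway == "SEXUAL"
  apo <- pathway %in% c("APOMICTIC", "Z_DOUBLED")
  lun <- pathway == "L_UNREDUCED_EGG"

  f_emb[sex] <- endosperm_x[sex] - embryo_x[sex]
  m_emb[sex] <- embryo_x[sex] - f_emb[sex]
  f_end[sex] <- 2 * f_emb[sex]
  m_end[sex] <- endosperm_x[sex] - f_end[sex]
  if (single_sperm_sexual) {
    # one sperm fertilizes the egg, the other the central cell; under the
    # equal-sperm assumption the numbers coincide, so this switch only
    # relabels how m_endosperm is interpreted (dosage of a single sperm).
    m_end[sex] <- endosperm_x[sex] - f_end[sex]
  }

  f_emb[apo] <- embryo_x[apo]
  m_emb[apo] <- 0
  f_end[apo] <- 2 * embryo_x[apo]
  m_end[apo] <- endosperm_x[apo] - 2 * embryo_x[apo]

  f_emb[lun] <- maternal_x[lun]
  m_emb[lun] <- embryo_x[lun] - maternal_x[lun]
  f_end[lun] <- 2 * maternal_x[lun]
  m_end[lun] <- endosperm_x[lun] - 2 * maternal_x[lun]

  comp <- cbind(f_emb, m_emb, f_end, m_end)
  too_neg <- rowSums(comp < -0.25, na.rm = TRUE) > 0
  if (any(too_neg)) {
    if (on_inconsistent == "error") {
      abort(paste0("inconsistent genomic contributions (component < -0.25x) ",
                   "violating the dosage identity for seed(s): ",
                   paste(seed_id[too_neg], collapse = ", ")))
    }
    comp[too_neg, ] <- NA_real_
  }
  clipped <- rowSums(comp < 0, na.rm = TRUE) > 0
  comp[comp < 0] <- 0
  tibble::tibble(f_embryo_x = unname(comp[, 1]),
                 m_embryo_x = unname(comp[, 2]),
                 f_endosperm_x = unname(comp[, 3]),
                 m_endosperm_x = unname(comp[, 4]),
                 clipped = clipped, inconsistent = too_neg)
}

#' Maternal:paternal endosperm dosage ratio
#'
#' Expresses the endosperm genome dosage as paternal units per two maternal
#' units (the `2m : p` convention of pseudogamous systems): returns
#' `2 * m_endosperm / f_endosperm`. A balanced sexually derived seed gives 1
#' (ratio 2m:1p); autonomous endosperm gives 0.
#'
#' @param f_endosperm_x,m_endosperm_x Female and male endosperm
#'   contributions (chromosome sets); `f_endosperm_x` must be positive.
#' @return Paternal dosage per two maternal units.
#' @export
endosperm_ratio <- function(f_endosperm_x, m_endosperm_x) {
  f <- as.numeric(f_endosperm_x); m <- as.numeric(m_endosperm_x)
  if (any(!is.na(f) & f <= 0))
    abort("female endosperm contribution must be positive for the 2m:p ratio")
  2 * m / f
}

#' Summarize seed calls per maternal plant
#'
#' Tallies pathway calls for each plant; a plant is `mixed` when it carries
#' both sexually derived (`SEXUAL`, `L_UNREDUCED_EGG`) and apomictic
#' (`APOMICTIC`, `Z_DOUBLED`) seeds. `UNKNOWN`/`FAILED` seeds are counted
#' but excluded from the mode tallies.
#'
#' @param calls A seed-call tibble with columns `plant_id`, `pathway` and
#'   (optionally) `population_id`, `maternal_ploidy_x`.
#' @param l_as_sexual,z_as_apomictic Whether the irregular pathways count
#'   towards the sexual/apomictic mode tallies (defaults `TRUE`).
#' @return A tibble with one row per plant: pathway counts `n_sexual`,
#'   `n_apomictic`, `n_l`, `n_z`, `n_unknown`, `n_failed`, `n_seeds`,
#'   `n_informative` and logical `mixed`.
#' @export
summarize_plants <- function(calls, l_as_sexual = TRUE, z_as_apomictic = TRUE) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(plant_id = character(), n_sexual = integer(),
                          n_apomictic = integer(), n_l = integer(),
                          n_z = integer(), n_unknown = integer(),
                          n_failed = integer(), n_seeds = integer(),
                          n_informative = integer(), mixed = logical()))
  }
  keys <- intersect(c("plant_id", "population_id", "maternal_ploidy_x"),
                    names(calls))
  out <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_sexual = sum(.data$pathway == "SEXUAL") +
        if (l_as_sexual) sum(.data$pathway == "L_UNREDUCED_EGG") else 0L,
      n_apomictic = sum(.data$pathway == "APOMICTIC") +
        if (z_as_apomictic) sum(.data$pathway == "Z_DOUBLED") else 0L,
      n_l = sum(.data$pathway == "L_UNREDUCED_EGG"),
      n_z = sum(.data$pathway == "Z_DOUBLED"),
      n_unknown = sum(.data$pathway == "UNKNOWN"),
      n_failed = sum(.data$pathway == "FAILED"),
      n_seeds = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(
      n_informative = .data$n_sexual + .data$n_apomictic,
      mixed = .data$n_sexual >= 1L & .data$n_apomictic >= 1L)
  out
}
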