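#' Fulton's condition factor
#'
#' `100 * body_mass / fork_length^3` with mass in grams and fork length in
#' centimetres.
#'
#' @param body_mass_g Body mass, g.
#' @param fork_length_cm Fork length, cm.
#' @return Condition factor (dimensionless). Vectorised.
#' @export
condition_factor <- function(body_mass_g, fork_length_cm) {
  if (any(body_mass_g <= 0) || any(fork_length_cm <= 0)) {
    stop("mass and length must be positive", call. = FALSE)
  }
  100 * body_mass_g / fork_length_cm^3
}

#' Organ and haematological indices
#'
#' Adds to each fish record:
#' * splenosomatic index = spleen mass / body mass x 100;
#' * relative ventricle mass = wet ventricle mass / body mass x 100;
#' * relative compact mass = dry compact myocardial mass / dry ventricular
#'   mass x 100 (dry ventricular mass = dried compact + dried spongy);
#' * MCHC = \[Hb\] / Hct, in g l-1 per % haematocrit (Hct kept on its
#'   percentage scale, as conventionally reported);
#' * condition factor, when fork length is present.
#'
#' @param records Data frame with columns `body_mass_g`, and any of
#'   `fork_length_cm`, `spleen_mass_g`, `ventricle_wet_mass_g`,
#'   `compact_dry_mass_g`, `spongy_dry_mass_g` (or `ventricle_dry_mass_g`),
#'   `hb_g_l`, `hct_pct`.
#' @return The records with index columns appended.
#' @export
organ_indices <- function(records) {
  r <- tibble::as_tibble(records)
  if (any(r$body_mass_g <= 0)) stop("body mass must be positive", call. = FALSE)
  if (all(c("fork_length_cm") %in% names(r))) {
    r$condition_factor <- condition_factor(r$body_mass_g, r$fork_length_cm)
  }
  if ("spleen_mass_g" %in% names(r)) {
    r$splenosomatic_index <- r$spleen_mass_g / r$body_mass_g * 100
  }
  if ("ventricle_wet_mass_g" %in% names(r)) {
    r$relative_ventricle_mass <- r$ventricle_wet_mass_g / r$body_mass_g * 100
  }
  if ("compact_dry_mass_g" %in% names(r)) {
    vdm <- if ("ventricle_dry_mass_g" %in% names(r)) r$ventricle_dry_mass_g
           else r$compact_dry_mass_g + r$spongy_dry_mass_g
    if (any(r$compact_dry_mass_g > vdm + 1e-12)) {
      stop("compact dry mass exceeds ventricular dry mass", call. = FALSE)
    }
    r$relative_compact_mass <- r$compact_dry_mass_g / vdm * 100
  }
  if (all(c("hb_g_l", "hct_pct") %in% names(r))) {
    if (any(r$hct_pct <= 0 | r$hct_pct >= 100)) {
      stop("hct_pct must lie in (0, 100)", call. = FALSE)
    }
    r$mchc <- r$hb_g_l / r$hct_pct
  }
  r
}

#' Apply haematological exclusion rules
#'
#' Discards anaemic fish, defined by haematocrit strictly below 20%; a fish
#' at exactly 20.0 is retained. Every removal is logged with the rule that
#' fired, and the audit identity (input rows = output rows + logged
#' removals) always holds.
#'
#' @param records Data frame with an `hct_pct` column (and ideally an id
#'   column such as `fish_id`).
#' @param hct_min Anaemia threshold, default 20 (strict `<`).
#' @return The retained records, with the removal log as attribute
#'   `"exclusions"` (tibble: `fish_id`, `rule`, `value`).
#' @export
apply_exclusions <- function(records, hct_min = 20) {
  r <- tibble::as_tibble(records)
  id <- if ("fish_id" %in% names(r)) r$fish_id else seq_len(nrow(r))
  drop <- !is.na(r$hct_pct) & r$hct_pct < hct_min
  log <- tibble::tibble(fish_id = id[drop], rule = "anaemia_hct_lt_20",
                        value = r$hct_pct[drop])
  out <- r[!drop, ]
  attr(out, "exclusions") <- log
  out
}
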