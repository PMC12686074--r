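#' Read a per-variant free-energy-change table
#'
#' Ingests one predictor's mutation-induced stability changes for one
#' conformational state, normalizing values to the package's internal sign
#' convention: **negative = destabilizing**. Predictors disagree on sign
#' conventions, so each input must declare its own; values from a
#' `positive_is_destabilizing` source are sign-flipped on ingestion
#' (flipping twice is the identity).
#'
#' @param path TSV/CSV with a variant-key column and a value column.
#' @param predictor One of `"pyrosetta_like"`, `"SDM"`, `"mCSM"`,
#'   `"DUET"`, `"DDMut"`, `"Dynamut2"`, `"other"`.
#' @param state Conformational state: `"open"` or `"closed"`.
#' @param convention `"negative_is_destabilizing"` (kept as-is) or
#'   `"positive_is_destabilizing"` (sign-flipped).
#' @param columns Named list as in [read_score_table()]; the value column
#'   defaults to `"ddg"`.
#' @return Tibble with columns `variant`, `position`, `ref_aa`, `alt_aa`,
#'   `predictor`, `state`, `ddg` (internal convention).
#' @export
read_ddg_table <- function(path, predictor = c("pyrosetta_like", "SDM", "mCSM",
                                               "DUET", "DDMut", "Dynamut2",
                                               "other"),
                           state = c("open", "closed"),
                           convention = c("negative_is_destabilizing",
                                          "positive_is_destabilizing"),
                           columns = list(variant = "variant", value = "ddg")) {
  predictor <- match.arg(predictor)
  state <- match.arg(state)
  convention <- match.arg(convention)
  raw <- read_delim_auto(path)
  tab <- score_table_from_df(raw, feature = "ddG", orientation = "lower_is_damaging",
                             columns = columns, source = path)
  ddg <- tab$value
  if (convention == "positive_is_destabilizing") ddg <- -ddg
  if (any(!is.finite(ddg))) abort(sprintf("Non-finite ddG value in %s.", path))
  tibble(variant = tab$variant, position = tab$position,
         ref_aa = tab$ref_aa, alt_aa = tab$alt_aa,
         predictor = predictor, state = state, ddg = ddg)
}

STABILITY_CLASSES <- c("destabilizes_both", "destabilizes_closed_only",
                       "destabilizes_open_only", "open_shift_stabilizing",
                       "neutral", "ambiguous")

#' Classify a variant's dual-state stability pattern
#'
#' Maps a pair of free-energy changes (internal convention, negative =
#' destabilizing) for the open and closed conformations to one of five
#' mutually exclusive classes, given a magnitude threshold `tau`:
#'
#' * `open_shift_stabilizing` — open-state value \eqn{\ge +\tau}{>= +tau}
#'   (the variant stabilizes the catalytically active conformation; takes
#'   precedence over any closed-state destabilization, mirroring the
#'   interpretation of open-shift gain-of-function variants);
#' * `destabilizes_both` — both values \eqn{\le -\tau};
#' * `destabilizes_closed_only` / `destabilizes_open_only` — only that
#'   state at or beyond \eqn{-\tau};
#' * `neutral` — everything else (both within the band, including a
#'   stabilized closed state).
#'
#' The classification is exhaustive and mutually exclusive over the plane.
#' With `detail = TRUE`, the compound pattern of a destabilized closed
#' state together with a stabilized open state is reported as
#' `"closed_destab_open_shift"` (it still maps to `open_shift_stabilizing`
#' in the plain classification used for consensus voting).
#'
#' @param ddg_open,ddg_closed Numeric vectors (recycled), internal sign
#'   convention.
#' @param tau Positive threshold in the tabulated energy units (default 1).
#' @param detail If `TRUE`, report compound patterns.
#' @return Character vector of classes.
#' @export
classify_stability <- function(ddg_open, ddg_closed, tau = 1, detail = FALSE) {
  assert_scalar_number(tau, "tau", positive = TRUE)
  n <- max(length(ddg_open), length(ddg_closed))
  o <- rep_len(ddg_open, n); c_ <- rep_len(ddg_closed, n)
  if (any(!is.finite(o)) || any(!is.finite(c_))) {
    abort("classify_stability() requires finite ddG values.")
  }
  cls <- ifelse(o >= tau, "open_shift_stabilizing",
         ifelse(o <= -tau & c_ <= -tau, "destabilizes_both",
         ifelse(c_ <= -tau, "destabilizes_closed_only",
         ifelse(o <= -tau, "destabilizes_open_only", "neutral"))))
  if (detail) {
    cls[o >= tau & c_ <= -tau] <- "closed_destab_open_shift"
  }
  cls
}

#' Consensus stability class across predictors
#'
#' Strict-majority vote over per-predictor classes; if no class holds a
#' strict majority the consensus is `"ambiguous"`. The vote is invariant
#' to predictor order.
#'
#' @param classes Character vector of per-predictor classes.
#' @return A single class string.
#' @export
consensus_stability <- function(classes) {
  if (length(classes) == 0L) abort("No predictor classes supplied.")
  tab <- table(classes)
  top <- max(tab)
  if (top > length(classes) / 2) names(tab)[which.max(tab)] else "ambiguous"
}

#' Build dual-state stability profiles
#'
#' Combines per-predictor, per-state free-energy-change records (from
#' [read_ddg_table()]) into one row per variant and predictor with the
#' open and closed values side by side, the per-predictor class, and a
#' per-variant consensus class by strict-majority vote.
#'
#' @param ddg_records Tibble of rows from [read_ddg_table()] (possibly
#'   several predictors and both states, row-bound).
#' @param tau Classification threshold passed to [classify_stability()].
#' @return A list with `profile` (tibble: variant, predictor, ddg_open,
#'   ddg_closed, class, detail_class) and `consensus` (tibble: variant,
#'   consensus_class).
#' @export
dual_state_profile <- function(ddg_records, tau = 1) {
  stopifnot(is.data.frame(ddg_records),
            all(c("variant", "predictor", "state", "ddg") %in% names(ddg_records)))
  wide <- ddg_records |>
    select("variant", "predictor", "state", "ddg") |>
    tidyr::pivot_wider(names_from = "state", values_from = "ddg",
                       names_prefix = "ddg_")
  if (!all(c("ddg_open", "ddg_closed") %in% names(wide))) {
    missing_state <- setdiff(c("ddg_open", "ddg_closed"), names(wide))
    abort(sprintf("Records lack any '%s' state values.",
                  sub("ddg_", "", missing_state[1])))
  }
  complete <- !is.na(wide$ddg_open) & !is.na(wide$ddg_closed)
  prof <- wide[complete, , drop = FALSE] |>
    mutate(
      class = classify_stability(.data$ddg_open, .data$ddg_closed, tau = tau),
      detail_class = classify_stability(.data$ddg_open, .data$ddg_closed,
                                        tau = tau, detail = TRUE)
    ) |>
    arrange(.data$variant, .data$predictor)
  consensus <- prof |>
    group_by(.data$variant) |>
    summarise(consensus_class = consensus_stability(.data$class),
              n_predictors = n(), .groups = "drop")
  list(profile = prof, consensus = consensus)
}

#' Read ligand-affinity change records
#'
#' Ingests predicted ligand-affinity changes expressed as
#' \eqn{-\log_{10}(K_D/K_i)} (mCSM-lig style). A variant is flagged as
#' `binding_altered` when the absolute value is at least `tau_lig`
#' (inclusive at the boundary).
#'
#' @param path TSV/CSV with variant-key and value columns.
#' @param tau_lig Non-negative flag threshold; the default 0.5
#'   corresponds to roughly a 3-fold affinity change.
#' @param ligand Ligand identifier recorded on every row (e.g. `"ADP"`).
#' @param columns Column mapping as in [read_score_table()].
#' @return Tibble: `variant`, `ligand`, `value`, `binding_altered`.
#' @export
read_ligand_affinity <- function(path, tau_lig = 0.5, ligand = "ADP",
                                 columns = list(variant = "variant",
                                                value = "value")) {
  assert_scalar_number(tau_lig, "tau_lig")
  raw <- read_delim_auto(path)
  tab <- score_table_from_df(raw, feature = "ligand_affinity",
                             orientation = "higher_is_damaging",
                             columns = columns, source = path)
  if (any(!is.finite(tab$value))) abort(sprintf("Non-finite value in %s.", path))
  tibble(variant = tab$variant, ligand = ligand, value = tab$value,
         binding_altered = abs(tab$value) >= tau_lig)
}

#' Read interaction free-energy-change records
#'
#' Ingests per-variant binding free-energy changes for a protein–protein
#' interaction (e.g. the kinase-inhibitory-region interaction of a SOCS
#' regulator), in the internal sign convention after declaration, and
#' flags variants predicted to destabilize the interaction
#' (value \eqn{\le -\tau}).
#'
#' @inheritParams read_ddg_table
#' @param partner Interaction partner identifier.
#' @param tau Positive flag threshold.
#' @return Tibble: `variant`, `partner`, `ddg`, `destabilizes_interaction`.
#' @export
read_interaction_ddg <- function(path, partner, tau = 1,
                                 convention = c("negative_is_destabilizing",
                                                "positive_is_destabilizing"),
                                 columns = list(variant = "variant",
                                                value = "ddg")) {
  assert_scalar_number(tau, "tau", positive = TRUE)
  convention <- match.arg(convention)
  raw <- read_delim_auto(path)
  tab <- score_table_from_df(raw, feature = "interaction_ddg",
                             orientation = "lower_is_damaging",
                             columns = columns, source = path)
  ddg <- if (convention == "positive_is_destabilizing") -tab$value else tab$value
  tibble(variant = tab$variant, partner = partner, ddg = ddg,
         destabilizes_interaction = ddg <= -tau)
}
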