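# Theoretical ion m/z for the soft chemical-ionization reaction
# channels of PTR-ToF-MS (H3O+, O2+, NO+ reagent ions) and
# tolerance-based assignment of measured peaks to candidate formulas.
#
# Reagent-ion chemistry and the resulting product-ion mass offsets:
#   protonation          H3O+ + M -> MH+  + H2O    label = M + m(H)
#   charge_transfer      O2+  + M -> M+   + O2     label = M
#   hydride_abstraction  NO+  + MH -> M+  + HNO    label = M - m(H)
#   hydroxide_abstraction NO+ + MOH -> M+ + HONO   label = M - m(OH)
#   no_cluster           NO+  + M -> M.NO+         label = M + m(NO)
#
# "label" bookkeeping adds/removes neutral-atom masses (the
# convention commonly used when printing PTR-MS peak labels; the
# electron mass is neglected). "physical" additionally subtracts one
# electron mass per unit positive charge.

# most-abundant-isotope atomic masses, u
ATOMIC_MASSES <- c(
  H = 1.0078250,
  C = 12.0,
  N = 14.0030740,
  O = 15.9949146,
  S = 31.9720707
)
ELECTRON_MASS <- 0.00054858

ION_MODES <- c("protonation", "charge_transfer", "hydride_abstraction",
               "hydroxide_abstraction", "no_cluster")

#' Parse a molecular sum formula
#'
#' Accepts Hill-style strings like `"C10H16"` or `"CH4S"` (elements C,
#' H, N, O, S; counts default to 1) and returns a named integer vector.
#' Named numeric vectors pass through after validation.
#'
#' @param formula Character scalar or named numeric vector.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C10H16O")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else if (is.character(formula) && length(formula) == 1L) {
    if (!nzchar(formula) || grepl("[^A-Za-z0-9]", formula))
      cf_stop_input(sprintf("malformed sum formula '%s'", formula))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
    parts <- regmatches(formula, list(m))[[1]]
    if (sum(nchar(parts)) != nchar(formula))
      cf_stop_input(sprintf("malformed sum formula '%s'", formula))
    el <- sub("[0-9]*$", "", parts)
    ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                            sub("^[A-Za-z]+", "", parts), "1"))
    counts <- tapply(ct, el, sum)
    counts <- setNames(as.numeric(counts), names(counts))
  } else {
    cf_stop_input("`formula` must be a formula string or named count vector")
  }
  bad <- setdiff(names(counts), names(ATOMIC_MASSES))
  if (length(bad))
    cf_stop(sprintf("unsupported element symbol(s): %s",
                    paste(bad, collapse = ", ")), "cf_lookup_error")
  if (any(counts < 0) || any(counts != floor(counts)))
    cf_stop_input("element counts must be non-negative integers")
  if (sum(counts) == 0)
    cf_stop_input("formula must contain at least one atom")
  counts
}

#' Monoisotopic (most-abundant-isotope) molecular mass
#'
#' @param formula Sum formula (string or named count vector); see
#'   [parse_formula()].
#' @return Mass in u.
#' @examples
#' monoisotopic_mass("CH4O")   # 32.02621
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(ATOMIC_MASSES[names(counts)] * counts)
}

mode_delta <- function(mode) {
  switch(mode,
    protonation = ATOMIC_MASSES[["H"]],
    charge_transfer = 0,
    hydride_abstraction = -ATOMIC_MASSES[["H"]],
    hydroxide_abstraction = -(ATOMIC_MASSES[["O"]] + ATOMIC_MASSES[["H"]]),
    no_cluster = ATOMIC_MASSES[["N"]] + ATOMIC_MASSES[["O"]]
  )
}

check_mode_allowed <- function(counts, mode) {
  h <- if ("H" %in% names(counts)) counts[["H"]] else 0
  o <- if ("O" %in% names(counts)) counts[["O"]] else 0
  if (mode == "hydride_abstraction" && h < 1)
    cf_stop(sprintf("hydride abstraction requires >= 1 H"), "cf_mode_error")
  if (mode == "hydroxide_abstraction" && (h < 1 || o < 1))
    cf_stop("hydroxide abstraction requires >= 1 O and >= 1 H", "cf_mode_error")
  invisible(TRUE)
}

#' Theoretical product-ion m/z for a soft-ionization channel
#'
#' Computes the m/z of the product ion formed from a neutral of the
#' given sum formula under one of the reaction channels (see Details in
#' the package docs). Under the default `"label"` convention the
#' offsets are neutral-atom masses (protonation adds 1.007825 u,
#' the hydrogen-atom mass); the `"physical"` convention additionally
#' subtracts one electron mass (0.00054858 u), so protonation adds the
#' true proton mass 1.007276 u.
#'
#' @param formula Neutral sum formula (string or named counts).
#' @param mode One of `"protonation"`, `"charge_transfer"`,
#'   `"hydride_abstraction"`, `"hydroxide_abstraction"`, `"no_cluster"`.
#' @param convention `"label"` (default) or `"physical"`.
#' @return m/z in u (full precision; see [mz_label()] for the rounded
#'   3-decimal peak label).
#' @examples
#' mz_label(ion_mz("CH4O", "protonation"))   # 33.034, protonated methanol
#' mz_label(ion_mz("C10H16", "protonation")) # 137.133, monoterpenes
#' @export
ion_mz <- function(formula, mode = ION_MODES, convention = c("label", "physical")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  counts <- parse_formula(formula)
  check_mode_allowed(counts, mode)
  mz <- sum(ATOMIC_MASSES[names(counts)] * counts) + mode_delta(mode)
  if (convention == "physical") mz <- mz - ELECTRON_MASS
  unname(mz)
}

#' Round an m/z to its printed 3-decimal peak label (half-up)
#'
#' Peak labels round half-up, not to even: 153.1279... prints 153.128.
#'
#' @param mz Numeric m/z value(s).
#' @param digits Decimals (default 3).
#' @return Rounded numeric.
#' @export
mz_label <- function(mz, digits = 3) {
  p <- 10^digits
  floor(mz * p + 0.5) / p
}

#' Ion species: formula + ionization channel + theoretical m/z
#'
#' @param formula Neutral sum formula.
#' @param mode Ionization channel (see [ion_mz()]).
#' @param convention m/z convention (see [ion_mz()]).
#' @param label Optional display label; defaults to `formula-mode`.
#' @return Object of class `ion_species` with fields `neutral`, `mode`,
#'   `mz`, `convention`, `label`.
#' @export
ion_species <- function(formula, mode = ION_MODES,
                        convention = c("label", "physical"),
                        label = NULL) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  counts <- parse_formula(formula)
  mz <- ion_mz(counts, mode, convention)
  if (is.null(label))
    label <- paste0(if (is.character(formula)) formula else
      paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = ""),
      " [", mode, "]")
  structure(list(neutral = counts, mode = mode, mz = mz,
                 convention = convention, label = label),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s: m/z %.3f (%s)\n", x$label, mz_label(x$mz),
              x$convention))
  invisible(x)
}

#' Assign a measured peak to candidate ion species
#'
#' Ranks all candidates whose theoretical m/z lies within `tolerance_mDa`
#' of the measured value by ascending absolute mass error.
#'
#' @param measured_mz Measured m/z, u.
#' @param candidates List of [ion_species()] objects.
#' @param tolerance_mDa Match window, milli-dalton (default 5).
#' @return A data.frame (possibly 0-row) with columns `label`, `mode`,
#'   `mz`, `error_mDa`, sorted by `abs(error_mDa)`.
#' @export
assign_peak <- function(measured_mz, candidates, tolerance_mDa = 5) {
  if (!is.finite(tolerance_mDa) || tolerance_mDa <= 0)
    cf_stop_invalid("`tolerance_mDa` must be positive")
  if (inherits(candidates, "ion_species")) candidates <- list(candidates)
  mz <- vapply(candidates, `[[`, numeric(1), "mz")
  err <- (measured_mz - mz) * 1e3
  sel <- abs(err) <= tolerance_mDa
  out <- data.frame(
    label = vapply(candidates, `[[`, character(1), "label")[sel],
    mode = vapply(candidates, `[[`, character(1), "mode")[sel],
    mz = mz[sel], error_mDa = err[sel],
    stringsAsFactors = FALSE
  )
  out[order(abs(out$error_mDa)), , drop = FALSE]
}

#' Read / write candidate ion sets as delimited text
#'
#' Tab-separated columns: `formula`, `mode`, `label` (label optional).
#'
#' @param path File path.
#' @param convention Passed to [ion_species()].
#' @return `read_candidates()`: list of `ion_species`.
#' @export
read_candidates <- function(path, convention = "label") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("formula", "mode") %in% names(df)))
    cf_stop_validation(sprintf("%s: candidate file needs columns formula, mode", path))
  lapply(seq_len(nrow(df)), function(i)
    ion_species(df$formula[i], df$mode[i], convention,
                label = if ("label" %in% names(df)) df$label[i] else NULL))
}

#' @param candidates List of [ion_species()] to write.
#' @rdname read_candidates
#' @export
write_candidates <- function(candidates, path) {
  df <- data.frame(
    formula = vapply(candidates, function(x)
      paste0(names(x$neutral), ifelse(x$neutral > 1, x$neutral, ""),
             collapse = ""), character(1)),
    mode = vapply(candidates, `[[`, character(1), "mode"),
    label = vapply(candidates, `[[`, character(1), "label")
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
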