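# Exact-mass arithmetic for ynone (alkynylketone) probes and their covalent
# protein adducts. All masses are monoisotopic, in daltons, computed from the
# frozen atomic-mass table below so that results are independent of any
# external mass library.

# Monoisotopic atomic masses (CODATA/IUPAC 2021), frozen in-module.
ATOMIC_MONOISOTOPIC <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  Si = 27.9769265325,
  P  = 30.97376199842,
  F  = 18.99840316273,
  Cl = 34.968852682,
  Br = 78.9183376,
  I  = 126.9044719,
  Na = 22.98976928,
  K  = 38.9637064864
)

#' Parse a molecular formula
#'
#' Parses a Hill-style formula string (concatenated element tokens, each
#' optionally followed by an integer count) into a named integer vector of
#' element counts. The empty string is a valid formula of mass zero.
#'
#' @param text Formula string, e.g. `"C17H22O"` or `"C23H45O2Si"`.
#' @return An object of class `mol_formula`: a named integer vector of
#'   per-element counts in canonical Hill order (C, H, then other elements
#'   alphabetically).
#' @examples
#' parse_formula("C10H8")
#' parse_formula("C23H45O2Si")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  counts <- integer(0)
  if (nzchar(text)) {
    tokens <- stringr::str_match_all(text, "([A-Z][a-z]?)([0-9]*)")[[1]]
    consumed <- paste0(tokens[, 1], collapse = "")
    if (!identical(consumed, text)) {
      stop("malformed formula: ", sQuote(text), call. = FALSE)
    }
    for (i in seq_len(nrow(tokens))) {
      el <- tokens[i, 2]
      if (!el %in% names(ATOMIC_MONOISOTOPIC)) {
        stop("unknown element symbol ", sQuote(el), " in ", sQuote(text),
             call. = FALSE)
      }
      n <- tokens[i, 3]
      n <- if (nzchar(n)) as.integer(n) else 1L
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    }
    counts <- counts[counts > 0L]
  }
  structure(as.integer(counts), names = names(counts), class = "mol_formula")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format_formula(x), "  (",
      format(round(monoisotopic_mass(x), 4), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "mol_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  stop("expected a formula string or a mol_formula object", call. = FALSE)
}

#' Format a molecular formula in Hill order
#'
#' @param f A `mol_formula` or formula string.
#' @return A single string: carbon first, hydrogen second, remaining elements
#'   alphabetically; counts of 1 are omitted.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return("")
  els <- names(f)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(el) {
    n <- f[[el]]
    paste0(el, if (n > 1L) n else "")
  }, character(1)), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Plain sum of element counts times frozen monoisotopic atomic masses; no
#' electron-mass correction is applied, matching the convention of printed
#' high-resolution MS "calcd" values.
#'
#' @inheritParams format_formula
#' @return Mass in daltons.
#' @examples
#' monoisotopic_mass("H2O")    # 18.0106
#' monoisotopic_mass("C10H8")  # 128.0626
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  sum(ATOMIC_MONOISOTOPIC[names(f)] * as.numeric(f))
}

# round half away from zero at `digits` decimals (HRMS reporting convention)
round_half_away <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Calculated ion m/z
#'
#' m/z for an ion formula written as the ion (an `[M+H]+` formula already
#' includes the extra hydrogen), reported to four decimals with
#' round-half-away-from-zero, the convention of printed HRMS calcd values.
#'
#' @param ion_formula Ion formula (string or `mol_formula`).
#' @param charge Positive integer charge; default 1.
#' @return m/z in daltons per unit charge, rounded to 4 decimals.
#' @examples
#' ion_mz_calcd("C9H11O")   # 135.0810, the [M+H]+ ion of a C9 diynone
#' ion_mz_calcd("C17H27O")  # 247.2062
#' @export
ion_mz_calcd <- function(ion_formula, charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != as.integer(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  round_half_away(monoisotopic_mass(ion_formula) / charge, 4L)
}

#' Michael-adduct mass shift of an ynone probe
#'
#' Thiol or amine addition onto the terminal alkyne of an ynone adds the
#' entire neutral probe with no neutral loss, so the per-adduct mass shift
#' equals the probe's monoisotopic mass.
#'
#' @param probe Neutral probe formula (string or `mol_formula`).
#' @return A list with `exact` (daltons) and `nominal` (nearest integer Da).
#' @examples
#' michael_adduct_shift("C17H22O")  # exact 242.1671, nominal 242
#' @export
michael_adduct_shift <- function(probe) {
  m <- monoisotopic_mass(probe)
  list(exact = m, nominal = as.integer(round(m)))
}

#' isoDTB tag masses
#'
#' Mass added beyond the probe by CuAAC ligation of the light or heavy
#' desthiobiotin-azide tag. Defaults are back-derived from the printed
#' modification offsets of the C10 clickable diynone probe
#' (+625.3332 / +631.3404 Da light/heavy minus the probe mass 144.0575 Da).
#' The analogous printed light offset for the C17 probe is ~2 mDa lower than
#' probe mass + tag; the C10-derived values are treated as authoritative.
#'
#' @param light,heavy Tag masses in daltons; `heavy - light` must lie in
#'   (5.9, 6.1) Da (six 13C/15N-type label positions).
#' @return An `isodtb_tags` list with elements `light` and `heavy`.
#' @export
isodtb_tag_masses <- function(light = 481.2757, heavy = 487.2829) {
  stopifnot(is.numeric(light), is.numeric(heavy))
  d <- heavy - light
  if (!(d > 5.9 && d < 6.1)) {
    stop("heavy - light must lie in (5.9, 6.1) Da; got ", format(d),
         call. = FALSE)
  }
  structure(list(light = light, heavy = heavy), class = "isodtb_tags")
}

#' isoDTB modification offsets for a probe
#'
#' Total light/heavy mass added to a modified residue: probe monoisotopic
#' mass plus tag mass.
#'
#' @inheritParams michael_adduct_shift
#' @param tags An [isodtb_tag_masses()] object.
#' @return Tibble with one row: `light`, `heavy`, `delta` (heavy - light).
#' @examples
#' isodtb_offsets("C10H8O")   # 625.3332 / 631.3404
#' isodtb_offsets("C17H22O")
#' @export
isodtb_offsets <- function(probe, tags = isodtb_tag_masses()) {
  stopifnot(inherits(tags, "isodtb_tags"))
  m <- monoisotopic_mass(probe)
  tibble::tibble(
    probe = format_formula(as_formula(probe)),
    light = round_half_away(m + tags$light, 4L),
    heavy = round_half_away(m + tags$heavy, 4L),
    delta = round_half_away(tags$heavy - tags$light, 4L)
  )
}

#' Assign adduct stoichiometry on deconvoluted intact-protein masses
#'
#' Each observed deconvoluted peak is assigned the (base species, adduct
#' count) pair minimizing |peak - (base + n * shift)|, provided that minimum
#' is within `tol`; otherwise the peak is flagged unassigned. Ties are broken
#' by smaller adduct count, then by base order as given.
#'
#' @param base_masses Named numeric vector of unmodified species masses (Da),
#'   e.g. the two beta-lactoglobulin isoforms.
#' @param peaks Data frame with columns `mass_da` (strictly increasing) and
#'   `intensity` (non-negative), or a bare numeric vector of masses.
#' @param probe_shift Per-adduct mass shift in daltons (see
#'   [michael_adduct_shift()]).
#' @param max_adducts Maximum adduct count considered; default 4.
#' @param tol Assignment tolerance in daltons; default 0.5.
#' @return Tibble with one row per peak: `peak_mass`, `intensity`, `base_id`,
#'   `n_adducts`, `residual`, `assigned`.
#' @export
assign_adduct_stoichiometry <- function(base_masses, peaks, probe_shift,
                                        max_adducts = 4L, tol = 0.5) {
  if (length(base_masses) == 0L) stop("base_masses is empty", call. = FALSE)
  stopifnot(tol > 0, max_adducts >= 0)
  if (is.null(names(base_masses))) {
    names(base_masses) <- paste0("base", seq_along(base_masses))
  }
  if (is.numeric(peaks) && is.null(dim(peaks))) {
    peaks <- tibble::tibble(mass_da = as.numeric(peaks),
                            intensity = rep(NA_real_, length(peaks)))
  }
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("mass_da", "intensity") %in% names(peaks)))
  if (is.unsorted(peaks$mass_da, strictly = TRUE)) {
    stop("peak masses must be strictly increasing", call. = FALSE)
  }

  # candidate lattice: every (base, n) pair, n = 0..max_adducts
  grid <- tidyr::expand_grid(
    base_idx = seq_along(base_masses),
    n_adducts = 0:max_adducts
  )
  grid$expected <- base_masses[grid$base_idx] + grid$n_adducts * probe_shift

  purrr::pmap_dfr(
    list(peaks$mass_da, peaks$intensity),
    function(mass, intens) {
      resid <- mass - grid$expected
      # minimal |residual|, ties to smaller n then earlier base
      ord <- order(abs(resid), grid$n_adducts, grid$base_idx)
      best <- ord[1]
      ok <- abs(resid[best]) <= tol
      tibble::tibble(
        peak_mass = mass,
        intensity = intens,
        base_id = if (ok) names(base_masses)[grid$base_idx[best]] else NA_character_,
        n_adducts = if (ok) grid$n_adducts[best] else NA_integer_,
        residual = if (ok) resid[best] else NA_real_,
        assigned = ok
      )
    }
  )
}
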