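#' Parse a molecular formula string
#'
#' Parses Hill-style element + count notation ("C23H28F3N3O6S2") into a
#' named integer vector of element counts. An omitted count means one.
#' Repeated element symbols are summed.
#'
#' @param text A single non-empty formula string.
#' @return Named integer vector of counts, one entry per element.
#' @examples
#' parse_formula("C10H9F4NO6S2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("formula must be a single non-empty string")
  }
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    bad <- gsub("[A-Z][a-z]?[0-9]*", "", text)
    stop("cannot parse formula '", text, "': unexpected characters '",
         bad, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(.monoisotopic))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(n <= 0L)) {
    stop("element counts must be positive in '", text, "'")
  }
  counts <- tapply(n, el, sum)
  storage.mode(counts) <- "integer"
  # drop tapply's dimnames attribute, keep plain named vector
  c(counts)
}

#' Canonical Hill-order formula string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically
#' (all elements alphabetical when no carbon is present). Counts of one
#' are omitted, so the result round-trips through [parse_formula()].
#'
#' @param comp Named count vector as returned by [parse_formula()].
#' @return A single formula string.
#' @export
format_formula <- function(comp) {
  comp <- as_composition(comp)
  el <- names(comp)
  if ("C" %in% el) {
    ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  } else {
    ord <- sort(el)
  }
  n <- comp[ord]
  paste0(ord, ifelse(n == 1L, "", n), collapse = "")
}

# Coerce a formula string or named count vector to a validated composition.
as_composition <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("composition must be a named count vector or a formula string")
  }
  unknown <- setdiff(names(x), names(.monoisotopic))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(x <= 0) || any(x != round(x))) {
    stop("element counts must be positive integers")
  }
  storage.mode(x) <- "integer"
  x
}

#' Monoisotopic mass of a composition
#'
#' Sum of most-abundant-isotope masses times counts.
#'
#' @param comp Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C23H28F3N3O6S2") # 563.1372
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  sum(.monoisotopic[names(comp)] * comp)
}

#' Average (standard-atomic-weight) mass of a composition
#'
#' The mass scale of deconvoluted intact-protein spectra.
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in Da.
#' @export
average_mass <- function(comp) {
  comp <- as_composition(comp)
  sum(.atomic_weight[names(comp)] * comp)
}

#' m/z of a singly charged ion species
#'
#' Supported species: `"M+H"` (+1.00728 Da), `"M-H"` (-1.00728 Da),
#' `"M+Na"` (+22.98922 Da) and `"neutral"` (0). Offsets are cation/anion
#' masses, i.e. the electron mass is accounted for.
#'
#' @inheritParams monoisotopic_mass
#' @param species Ion species label.
#' @return m/z in Da (singly charged, so numerically a mass).
#' @examples
#' ion_mz("C23H28F3N3O6S2", "M+H") # 564.1444
#' @export
ion_mz <- function(comp, species = c("M+H", "M-H", "M+Na", "neutral")) {
  species <- match.arg(species)
  monoisotopic_mass(comp) + .ion_offsets[[species]]
}

#' Describe a (possibly covalent) compound
#'
#' Bundles a compound identifier with its molecular formula, warhead class
#' and, for ester/carbamate pre-vinylsulfones, the formula of the leaving
#' group eliminated on in-site activation (e.g. acetic acid C2H4O2 for the
#' acetate ester, phenylcarbamic acid C7H7NO2 for the phenylcarbamate).
#'
#' @param id Compound identifier (compound number or lab code).
#' @param formula Molecular formula string or count vector.
#' @param leaving_group Optional leaving-group formula; required for
#'   warhead classes `"ester"` and `"carbamate"` and must be an
#'   elementwise sub-composition of `formula`.
#' @param warhead_class One of `"ester"`, `"carbamate"`, `"vinylsulfone"`,
#'   `"none"`.
#' @param code Optional secondary identifier (synthesis lab code).
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(id, formula, leaving_group = NULL,
                            warhead_class = c("none", "ester", "carbamate",
                                              "vinylsulfone"),
                            code = NA_character_) {
  warhead_class <- match.arg(warhead_class)
  formula <- as_composition(formula)
  if (!is.null(leaving_group)) {
    leaving_group <- as_composition(leaving_group)
    extra <- setdiff(names(leaving_group), names(formula))
    if (length(extra) ||
        any(leaving_group > formula[names(leaving_group)])) {
      stop("leaving group is not a sub-composition of the formula for ",
           "compound ", id)
    }
  }
  if (warhead_class %in% c("ester", "carbamate") && is.null(leaving_group)) {
    stop("warhead class '", warhead_class, "' requires a leaving group (",
         id, ")")
  }
  structure(list(id = as.character(id), code = code, formula = formula,
                 leaving_group = leaving_group,
                 warhead_class = warhead_class),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat("<compound_record> ", x$id,
      if (!is.na(x$code)) paste0(" (", x$code, ")"),
      "\n  formula: ", format_formula(x$formula),
      "  warhead: ", x$warhead_class, "\n", sep = "")
  if (!is.null(x$leaving_group)) {
    cat("  leaving group: ", format_formula(x$leaving_group), "\n", sep = "")
  }
  invisible(x)
}

#' Predicted covalent-adduct mass shift
#'
#' The mass added to the protein on covalent modification: the compound
#' mass minus its leaving-group mass (the leaving group is eliminated
#' during in-site activation). A vinylsulfone warhead has no leaving
#' group and adds its full molecular mass.
#'
#' @param compound A [compound_record()].
#' @return Named numeric vector `c(monoisotopic = , average = )` in Da.
#' @examples
#' cpd22 <- compound_record("22", "C23H28F3N3O6S2",
#'                          leaving_group = "C7H7NO2",
#'                          warhead_class = "carbamate")
#' adduct_shift(cpd22)["monoisotopic"] # 426.0895
#' @export
adduct_shift <- function(compound) {
  stopifnot(inherits(compound, "compound_record"))
  if (compound$warhead_class == "none") {
    stop("compound ", compound$id, " is non-covalent: no adduct shift")
  }
  lg_mono <- lg_avg <- 0
  if (!is.null(compound$leaving_group)) {
    lg_mono <- monoisotopic_mass(compound$leaving_group)
    lg_avg <- average_mass(compound$leaving_group)
  } else if (compound$warhead_class != "vinylsulfone") {
    stop("compound ", compound$id, " has no leaving group")
  }
  c(monoisotopic = monoisotopic_mass(compound$formula) - lg_mono,
    average = average_mass(compound$formula) - lg_avg)
}

#' Expected masses of a multiply modified protein
#'
#' @param base Unmodified protein mass in Da.
#' @param shift Per-site adduct mass shift in Da.
#' @param max_sites Maximum number of modification sites (>= 1).
#' @return Numeric vector `base + (0:max_sites) * shift`.
#' @export
predict_modified_masses <- function(base, shift, max_sites) {
  stopifnot(base > 0, max_sites >= 1, max_sites == round(max_sites))
  base + (0:max_sites) * shift
}

#' Match observed protein mass shifts against candidate adducts
#'
#' For each deconvoluted peak the observed shift relative to the
#' unmodified-protein mass is compared with every candidate compound's
#' predicted average adduct shift (and its integer multiples up to
#' `max_sites`); the closest prediction within `tol` is reported.
#'
#' @param peaks Data frame with columns `mass_da` and `intensity`.
#' @param base Unmodified-protein peak mass in Da.
#' @param candidates List of [compound_record()] objects.
#' @param tol Match tolerance in Da (default 1.0; deconvoluted-mass
#'   differences commonly deviate from theory by several tenths of a Da).
#' @param max_sites Modification-site multiples to consider per candidate.
#' @return Data frame with one row per peak: `mass_da`, `intensity`,
#'   `observed_shift`, `candidate_id` (NA when unmatched), `n_sites`,
#'   `predicted_shift`, `error_da`, `error_ppm` (relative to peak mass).
#' @export
match_shift <- function(peaks, base, candidates, tol = 1.0, max_sites = 2L) {
  stopifnot(is.data.frame(peaks),
            all(c("mass_da", "intensity") %in% names(peaks)),
            all(peaks$mass_da > 0), all(peaks$intensity >= 0),
            tol > 0, base > 0)
  if (length(candidates) == 0L) stop("empty candidate list")
  stopifnot(all(vapply(candidates, inherits, TRUE, "compound_record")))

  pred <- do.call(rbind, lapply(candidates, function(cr) {
    s <- adduct_shift(cr)[["average"]]
    data.frame(candidate_id = cr$id, n_sites = seq_len(max_sites),
               predicted_shift = s * seq_len(max_sites))
  }))

  out <- lapply(seq_len(nrow(peaks)), function(i) {
    obs <- peaks$mass_da[i] - base
    err <- obs - pred$predicted_shift
    j <- which.min(abs(err))
    hit <- abs(err[j]) <= tol && abs(obs) > tol # base peak never matched
    data.frame(
      mass_da = peaks$mass_da[i], intensity = peaks$intensity[i],
      observed_shift = obs,
      candidate_id = if (hit) pred$candidate_id[j] else NA_character_,
      n_sites = if (hit) pred$n_sites[j] else NA_integer_,
      predicted_shift = if (hit) pred$predicted_shift[j] else NA_real_,
      error_da = if (hit) err[j] else NA_real_,
      error_ppm = if (hit) err[j] / peaks$mass_da[i] * 1e6 else NA_real_
    )
  })
  do.call(rbind, out)
}
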