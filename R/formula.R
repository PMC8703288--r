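#' Parse a molecular formula
#'
#' Parses a Hill-notation molecular formula (e.g. `"C3H9NO4S"`) into a named
#' integer vector of element counts. Only elements present in the package's
#' embedded isotope table (C, H, N, O, S, P, Na) are accepted.
#'
#' @param text A single non-empty formula string. Element symbols follow the
#'   usual one-capital(+optional lowercase) convention, each optionally
#'   followed by an integer count (default 1).
#'
#' @return A named integer vector of class `"formula_comp"`, one entry per
#'   element, in Hill order (C first, then H, then remaining elements
#'   alphabetically).
#'
#' @examples
#' parse_formula("C3H9NO4S")   # neutral cysteinolic acid
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty formula string", call. = FALSE)
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(matched)) != nchar(text)) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", matched)
  cnts <- sub("^[A-Z][a-z]?", "", matched)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  unknown <- setdiff(syms, .supported_elements())
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  comp <- as.integer(counts)
  names(comp) <- names(counts)
  new_formula_comp(comp)
}

new_formula_comp <- function(counts) {
  counts <- counts[counts != 0L]
  if (any(counts < 0L)) stop("negative element count", call. = FALSE)
  structure(counts[hill_order(names(counts))], class = "formula_comp")
}

hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  intersect(c("C", "H", rest), symbols)
}

#' @export
print.formula_comp <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Write a composition back to Hill notation
#'
#' Canonical writer: round-trips with [parse_formula()].
#'
#' @param comp A `formula_comp` or formula string.
#' @return A single formula string ("" for the empty composition).
#' @export
format_formula <- function(comp) {
  comp <- as_formula(comp)
  if (length(comp) == 0L) return("")
  paste0(names(comp), ifelse(unclass(comp) == 1L, "", unclass(comp)),
         collapse = "")
}

#' @rdname parse_formula
#' @param x A formula string or `formula_comp`.
#' @export
as_formula <- function(x) {
  if (inherits(x, "formula_comp")) return(x)
  if (is.character(x)) return(parse_formula(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a molecular formula", call. = FALSE)
}

#' Combine or subtract element compositions
#'
#' `formula_add()` returns the element-wise sum of two compositions;
#' `formula_subtract()` the element-wise difference, erroring if any count
#' would go negative (i.e. `b` is not a sub-formula of `a`).
#'
#' @param a,b Formula strings or `formula_comp` objects.
#' @return A `formula_comp`.
#' @export
formula_add <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    sum(c(unclass(a)[s], unclass(b)[s]), na.rm = TRUE)
  }, integer(1))
  new_formula_comp(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    as.integer(sum(unclass(a)[s], na.rm = TRUE) - sum(unclass(b)[s], na.rm = TRUE))
  }, integer(1))
  if (any(out < 0L)) {
    stop(format_formula(b), " is not contained in ", format_formula(a),
         call. = FALSE)
  }
  new_formula_comp(out)
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the mass of the element's most abundant
#' isotope, from the package's embedded atomic-mass table.
#'
#' @param comp A formula string or `formula_comp`. The empty composition has
#'   mass 0.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.010565
#' monoisotopic_mass("C3H9NO4S")  # 155.025230, neutral cysteinolic acid
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_formula(comp)
  if (length(comp) == 0L) return(0)
  masses <- vapply(names(comp), .monoisotopic_element_mass, numeric(1))
  sum(masses * unclass(comp))
}

#' Adduct specifications
#'
#' Returns the mass shift and charge of a named electrospray adduct. The
#' protonated adduct uses the proton mass (1.0072765 Da), i.e. cation m/z
#' values are electron-mass corrected.
#'
#' @param name One of `"[M+H]+"`, `"[M+Na]+"`, `"[M-H]-"`.
#' @return A list with `name`, `mass_shift` (Da) and `charge`.
#' @export
adduct <- function(name = "[M+H]+") {
  if (is.list(name) && all(c("name", "mass_shift", "charge") %in% names(name))) {
    return(name)
  }
  switch(name,
    "[M+H]+"  = list(name = "[M+H]+",  mass_shift = .proton_mass, charge = 1L),
    "[M+Na]+" = list(name = "[M+Na]+",
                     mass_shift = .isotope_table$Na$mass[1] - .electron_mass,
                     charge = 1L),
    "[M-H]-"  = list(name = "[M-H]-", mass_shift = -.proton_mass, charge = 1L),
    stop("unsupported adduct: ", name, call. = FALSE)
  )
}

#' m/z of an adduct ion
#'
#' `(monoisotopic_mass(comp) + mass_shift) / charge` for the requested adduct.
#'
#' @param comp Formula string or `formula_comp` of the neutral molecule.
#' @param adduct_name Adduct name or spec, see [adduct()].
#' @return m/z of the monoisotopic adduct ion.
#' @examples
#' adduct_mz("C3H9NO4S", "[M+H]+")  # 156.03251, protonated cysteinolic acid
#' @export
adduct_mz <- function(comp, adduct_name = "[M+H]+") {
  ad <- adduct(adduct_name)
  if (ad$charge < 1L) stop("adduct charge must be >= 1", call. = FALSE)
  (monoisotopic_mass(comp) + ad$mass_shift) / ad$charge
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
mass_error_ppm <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0", call. = FALSE)
  1e6 * (observed - theoretical) / theoretical
}
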