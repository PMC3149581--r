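# Molecular-formula mass calculus: formula parsing, monoisotopic masses,
# adduct m/z, ppm errors, tolerance-based annotation and the bundled
# tool-comparison report.

.amdorap_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "amdorap")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Monoisotopic atomic masses
#'
#' Returns the packaged table of monoisotopic atomic masses (most abundant
#' isotope, Da) used by all mass computations. Masses are stored to ten
#' decimal places so that computed adduct m/z values are reproducible
#' independent of any external chemistry library.
#'
#' @return A data frame with columns `element` and `mass` (Da).
#' @export
atomic_masses <- function() {
  if (is.null(.amdorap_cache$masses)) {
    .amdorap_cache$masses <- utils::read.delim(.extdata("atomic_masses.tsv"),
                                               stringsAsFactors = FALSE)
  }
  .amdorap_cache$masses
}

#' Supported ionization adducts
#'
#' The packaged adduct table. Each adduct maps a neutral monoisotopic mass to
#' an observed m/z via `(mass + delta_mass) / |charge|`. Deltas are
#' charge-aware: `[M+H]+` adds the proton mass 1.00727646 Da (hydrogen atom
#' minus one electron), `[M+Na]+` the sodium cation mass, and so on.
#'
#' @return A data frame with columns `adduct`, `delta_mass` (Da) and `charge`.
#' @export
adduct_table <- function() {
  if (is.null(.amdorap_cache$adducts)) {
    .amdorap_cache$adducts <- utils::read.delim(.extdata("adducts.tsv"),
                                                stringsAsFactors = FALSE)
  }
  .amdorap_cache$adducts
}

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula string (e.g. `"C3H7NO3"`) into a
#' named integer vector of element counts. A count of 1 may be implicit;
#' multi-digit counts are supported. Element symbols must appear in the
#' packaged atomic mass table ([atomic_masses()]); anything else is an error.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C3H7NO3")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  if (paste(toks, collapse = "") != text)
    stop("malformed formula string: '", text, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  if (any(n < 1L))
    stop("element count must be a positive integer in '", text, "'")
  known <- atomic_masses()$element
  bad <- setdiff(el, known)
  if (length(bad))
    stop("unknown element symbol(s) in '", text, "': ",
         paste(bad, collapse = ", "))
  counts <- tapply(n, factor(el, levels = unique(el)), sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a composition
#'
#' Sum of monoisotopic atomic masses over a parsed composition. Accepts a
#' formula string for convenience. The empty composition has mass 0.
#'
#' @param composition Named integer vector from [parse_formula()], or a
#'   formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0L) return(0)
  am <- atomic_masses()
  m <- am$mass[match(names(composition), am$element)]
  if (anyNA(m))
    stop("unknown element symbol(s): ",
         paste(names(composition)[is.na(m)], collapse = ", "))
  sum(m * as.numeric(composition))
}

#' m/z of an ionized adduct
#'
#' Applies an adduct's mass delta and charge to a neutral monoisotopic mass:
#' `(neutral_mass + delta) / |charge|`.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct Adduct name, one of `adduct_table()$adduct`
#'   (default `"[M+H]+"`).
#' @return m/z in Thomson.
#' @examples
#' adduct_mz(monoisotopic_mass("C3H7NO3"))  # serine [M+H]+, 106.04987
#' @export
adduct_mz <- function(neutral_mass, adduct = "[M+H]+") {
  ad <- adduct_table()
  i <- match(adduct, ad$adduct)
  if (is.na(i)) stop("unknown adduct: '", adduct, "'")
  (neutral_mass + ad$delta_mass[i]) / abs(ad$charge[i])
}

#' Theoretical adduct m/z from a molecular formula
#'
#' Convenience wrapper: parse, sum monoisotopic masses, ionize.
#'
#' @inheritParams parse_formula
#' @inheritParams adduct_mz
#' @return m/z in Thomson.
#' @export
formula_mz <- function(text, adduct = "[M+H]+") {
  adduct_mz(monoisotopic_mass(parse_formula(text)), adduct)
}

#' Signed mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`. Vectorized; arguments are
#' recycled as usual.
#'
#' @param observed Observed m/z (Thomson).
#' @param theoretical Theoretical m/z (Thomson), must be positive.
#' @return Signed error in ppm.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Annotate m/z values against a compound table
#'
#' Matches query m/z values against all (compound, adduct) theoretical m/z
#' within a ppm tolerance. All matches are returned — isobaric compounds
#' (identical formula, hence identical mass) each yield a row, since mass
#' alone cannot distinguish structural isomers or stereoisomers. Matches are
#' ordered by query, then by absolute ppm error.
#'
#' @param mz_values Numeric vector of query m/z values.
#' @param db Compound table: data frame with columns `name` and `formula`
#'   (see [load_compound_table()]).
#' @param adducts Character vector of adduct names to consider.
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @return Data frame with columns `query_mz`, `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `error_ppm`; zero rows if nothing matches.
#' @export
annotate <- function(mz_values, db, adducts = "[M+H]+", tol_ppm = 5) {
  stopifnot(is.numeric(mz_values), tol_ppm > 0)
  empty <- data.frame(query_mz = numeric(), name = character(),
                      formula = character(), adduct = character(),
                      theoretical_mz = numeric(), error_ppm = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(db) || nrow(db) == 0L || length(mz_values) == 0L) return(empty)
  theo <- unlist(lapply(adducts, function(a)
    vapply(db$formula, formula_mz, numeric(1), adduct = a)),
    use.names = FALSE)
  ref <- data.frame(name = rep(db$name, times = length(adducts)),
                    formula = rep(db$formula, times = length(adducts)),
                    adduct = rep(adducts, each = nrow(db)),
                    theoretical_mz = theo, stringsAsFactors = FALSE)
  out <- lapply(mz_values, function(q) {
    err <- ppm_error(q, ref$theoretical_mz)
    hit <- which(abs(err) <= tol_ppm)
    if (!length(hit)) return(NULL)
    hit <- hit[order(abs(err[hit]))]
    cbind(data.frame(query_mz = q), ref[hit, , drop = FALSE],
          data.frame(error_ppm = err[hit]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Bundled tool-comparison fixture
#'
#' Fourteen compounds identified in *Bacillus subtilis* extracts, with their
#' molecular formulas, theoretical `[M+H]+` m/z, and the observed m/z (and
#' published ppm errors) reported by three LC-MS processing approaches:
#' this method's single-step m/z grouping, MZmine 2, and XCMS. Values are
#' as printed in the published comparison (m/z to 5 decimals, ppm to 2).
#'
#' @return Data frame with one row per compound.
#' @export
tool_comparison <- function() {
  utils::read.delim(.extdata("tool_comparison.tsv"), stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Compare mass accuracy across processing tools
#'
#' For each compound row, recomputes the signed ppm error of every tool's
#' observed m/z against the theoretical m/z, then summarizes each tool by its
#' maximum absolute error and by the number of rows on which it is *strictly*
#' closest to theory (ties yield no winner).
#'
#' @param fixture A comparison table in the layout of [tool_comparison()]
#'   (columns `metabolite`, `formula`, `theoretical_mz`, and one
#'   `<tool>_mz` column per tool). Defaults to the bundled fixture.
#' @return An object of class `"tool_comparison"`: a list with `errors`
#'   (per-row signed ppm per tool), `max_abs_error` and `strict_wins`
#'   (named per tool).
#' @export
compare_tools <- function(fixture = tool_comparison()) {
  mz_cols <- grep("_mz$", names(fixture), value = TRUE)
  mz_cols <- setdiff(mz_cols, "theoretical_mz")
  if (!length(mz_cols)) stop("fixture has no <tool>_mz columns")
  tools <- sub("_mz$", "", mz_cols)
  err <- sapply(mz_cols, function(cl)
    ppm_error(fixture[[cl]], fixture$theoretical_mz))
  colnames(err) <- tools
  abs_err <- abs(err)
  winner <- apply(abs_err, 1L, function(r) {
    w <- which(r == min(r))
    if (length(w) == 1L) tools[w] else NA_character_
  })
  wins <- vapply(tools, function(t) sum(winner == t, na.rm = TRUE), integer(1))
  res <- list(
    errors = cbind(fixture[c("metabolite", "formula", "theoretical_mz")],
                   as.data.frame(err)),
    max_abs_error = apply(abs_err, 2L, max),
    strict_wins = wins,
    closest = winner)
  class(res) <- "tool_comparison"
  res
}

#' @export
print.tool_comparison <- function(x, ...) {
  cat("Mass-accuracy comparison over", nrow(x$errors), "compounds\n\n")
  tab <- x$errors
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.2f", v))
  tab$theoretical_mz <- sprintf("%.5f", x$errors$theoretical_mz)
  print(tab, row.names = FALSE)
  cat("\nmax |error| (ppm): ",
      paste(sprintf("%s %.2f", names(x$max_abs_error), x$max_abs_error),
            collapse = ", "), "\n", sep = "")
  cat("strictly closest (rows): ",
      paste(sprintf("%s %d", names(x$strict_wins), x$strict_wins),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
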