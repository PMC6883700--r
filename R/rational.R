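# Exact rational scalar helpers.  All exact values travel through the package
# as canonical strings "n" or "n/d"; arithmetic is delegated to the compiled
# arbitrary-precision core.

#' Convert printed decimals to exact rationals
#'
#' Converts decimal or fraction literals to exact rational strings:
#' `"1.5"` becomes `"3/2"`, `"1.0625e-4"` becomes `"17/160000"`.  A `snap`
#' table maps printed roundings back to the exact values a model declares
#' (e.g. `c("0.166" = "1/6")`); snapping is always explicit, never inferred.
#'
#' @param x character (or numeric) vector of literals
#' @param snap optional named character vector mapping printed literals to
#'   exact replacements, applied before conversion
#' @return character vector of canonical rational strings
#' @examples
#' rationalize("1.5")
#' rationalize("8.5")
#' rationalize("0.166", snap = c("0.166" = "1/6"))
#' @export
rationalize <- function(x, snap = NULL) {
  x <- as.character(x)
  if (!is.null(snap)) {
    stopifnot(!is.null(names(snap)))
    hit <- match(x, names(snap))
    x[!is.na(hit)] <- unname(snap[hit[!is.na(hit)]])
  }
  vapply(x, function(s) {
    tryCatch(cpp_rat_norm(s), error = function(e) {
      stop("not a numeric literal: '", s, "'", call. = FALSE)
    })
  }, character(1), USE.NAMES = FALSE)
}

#' Exact rational scalar arithmetic
#'
#' @param a,b rational strings (or numerics convertible via [rationalize()])
#' @return canonical rational string
#' @name rational-arith
#' @examples
#' ratAdd("1/3", "1/6")
#' ratMul("3/2", "2")
NULL

.rat <- function(x) if (is.character(x)) cpp_rat_norm(x) else rationalize(format(x, digits = 17))

#' @rdname rational-arith
#' @export
ratAdd <- function(a, b) cpp_rat_arith("add", .rat(a), .rat(b))

#' @rdname rational-arith
#' @export
ratSub <- function(a, b) cpp_rat_arith("sub", .rat(a), .rat(b))

#' @rdname rational-arith
#' @export
ratMul <- function(a, b) cpp_rat_arith("mul", .rat(a), .rat(b))

#' @rdname rational-arith
#' @export
ratDiv <- function(a, b) cpp_rat_arith("div", .rat(a), .rat(b))

#' Compare two exact rationals
#'
#' @param a,b rational strings
#' @return -1, 0 or 1
#' @export
ratCmp <- function(a, b) cpp_rat_cmp(.rat(a), .rat(b))

#' Convert exact rational strings to doubles
#'
#' @param x character vector of rational strings
#' @return numeric vector (rounded to nearest double)
#' @export
ratToNumeric <- function(x) cpp_rat_to_double(as.character(x))
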