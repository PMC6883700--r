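# Recursive-descent parser for the model expression grammar:
# identifiers, rational/decimal literals, + - * / ^ (integer exponents),
# parentheses.  Division by a non-constant polynomial produces a rational
# function (numerator/denominator pair) whose denominator is cleared before
# steady-state analysis.

.tokenize_expr <- function(text) {
  pat <- "([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?|[A-Za-z_][A-Za-z0-9_.]*|\\*|\\+|\\-|/|\\^|\\(|\\))"
  toks <- character()
  pos <- 1L
  s <- gsub("[[:space:]]", "", text)
  while (pos <= nchar(s)) {
    m <- regexpr(pat, substring(s, pos))
    if (m != 1) stop("cannot tokenize expression at: '", substring(s, pos), "'")
    len <- attr(m, "match.length")
    toks <- c(toks, substr(s, pos, pos + len - 1L))
    pos <- pos + len
  }
  toks
}

# rational function representation: list(num = QPolynomial, den = QPolynomial)
.rf_const <- function(vars, v) list(num = qpConst(vars, v), den = qpConst(vars, "1"))
.rf_poly  <- function(p) list(num = p, den = qpConst(p@vars, "1"))

.rf_simplify <- function(rf) {
  num <- rf$num
  den <- rf$den
  if (qpIsZero(num)) return(list(num = num, den = qpConst(num@vars, "1")))
  # constant denominator: fold into the numerator
  if (qpDegree(den) == 0L) {
    s <- cpp_rat_arith("div", "1", den@coefs[1])
    return(list(num = .qp_from_list(cpp_poly_scale(.qp_list(num), s), num@vars),
                den = qpConst(num@vars, "1")))
  }
  # full cancellation when the denominator divides the numerator
  q <- polyExactDivide(num, den)
  if (!is.null(q)) return(list(num = q, den = qpConst(num@vars, "1")))
  # strip a common monomial factor
  minN <- apply(num@exps, 2, min)
  minD <- apply(den@exps, 2, min)
  common <- pmin(minN, minD)
  if (any(common > 0)) {
    num@exps <- sweep(num@exps, 2, common)
    den@exps <- sweep(den@exps, 2, common)
    num <- .qp_canon(num)
    den <- .qp_canon(den)
  }
  # normalize the denominator's leading coefficient to 1 for a canonical form
  lc <- den@coefs[1]
  if (!identical(lc, "1")) {
    s <- cpp_rat_arith("div", "1", lc)
    num <- .qp_from_list(cpp_poly_scale(.qp_list(num), s), num@vars)
    den <- .qp_from_list(cpp_poly_scale(.qp_list(den), s), den@vars)
  }
  list(num = num, den = den)
}

.rf_add <- function(a, b, sub = FALSE) {
  sameden <- identical(a$den@exps, b$den@exps) && identical(a$den@coefs, b$den@coefs)
  bn <- if (sub) -b$num else b$num
  if (sameden) return(.rf_simplify(list(num = a$num + bn, den = a$den)))
  .rf_simplify(list(num = a$num * b$den + bn * a$den, den = a$den * b$den))
}

.rf_mul <- function(a, b) .rf_simplify(list(num = a$num * b$num, den = a$den * b$den))

.rf_div <- function(a, b) {
  if (qpIsZero(b$num)) stop("division by zero in model expression")
  .rf_simplify(list(num = a$num * b$den, den = a$den * b$num))
}

.rf_pow <- function(a, k) {
  if (k >= 0) return(.rf_simplify(list(num = a$num^k, den = a$den^k)))
  if (qpIsZero(a$num)) stop("zero raised to a negative power")
  .rf_simplify(list(num = a$den^(-k), den = a$num^(-k)))
}

#' Parse a model expression into a rational function
#'
#' Parses the model grammar (identifiers, rational/decimal literals,
#' `+ - * / ^` with integer exponents, parentheses) into an exact
#' numerator/denominator polynomial pair over `vars`.  Identifiers that are
#' not variables must be present in `params` and are substituted by their
#' exact rational values.  Non-rational constructs (e.g. `exp(x)`) are
#' rejected as unsupported models.
#'
#' @param text expression string, e.g. `"-beta*x1*x2/(K1+x1)"`
#' @param vars character vector of state variable names
#' @param params named character/numeric vector of parameter values
#' @param snap optional snap table passed to [rationalize()]
#' @return list with [QPolynomial] components `num` and `den`
#' @export
parseRationalExpression <- function(text, vars, params = character(), snap = NULL) {
  toks <- .tokenize_expr(text)
  i <- 0L
  peek <- function() if (i < length(toks)) toks[i + 1L] else ""
  advance <- function() {
    i <<- i + 1L
    toks[i]
  }
  expect <- function(tok) {
    got <- advance()
    if (!identical(got, tok)) stop("expected '", tok, "', got '", got, "' in: ", text)
  }
  parseExpr <- function() {
    acc <- parseTerm()
    while (peek() %in% c("+", "-")) {
      op <- advance()
      acc <- .rf_add(acc, parseTerm(), sub = identical(op, "-"))
    }
    acc
  }
  parseTerm <- function() {
    acc <- parseFactor()
    while (peek() %in% c("*", "/")) {
      op <- advance()
      rhs <- parseFactor()
      acc <- if (identical(op, "*")) .rf_mul(acc, rhs) else .rf_div(acc, rhs)
    }
    acc
  }
  parseFactor <- function() {
    if (peek() == "-") { advance(); return(.rf_mul(.rf_const(vars, "-1"), parseFactor())) }
    if (peek() == "+") { advance(); return(parseFactor()) }
    base <- parseBase()
    if (peek() == "^") {
      advance()
      neg <- FALSE
      if (peek() == "-") { advance(); neg <- TRUE }
      etok <- advance()
      if (!grepl("^[0-9]+$", etok)) stop("exponent must be an integer in: ", text)
      k <- as.integer(etok)
      base <- .rf_pow(base, if (neg) -k else k)
    }
    base
  }
  parseBase <- function() {
    tok <- advance()
    if (identical(tok, "(")) {
      inner <- parseExpr()
      expect(")")
      return(inner)
    }
    if (grepl("^[0-9.]", tok)) return(.rf_const(vars, rationalize(tok, snap)))
    if (tok %in% vars) return(.rf_poly(qpVar(vars, tok)))
    if (tok %in% names(params)) {
      return(.rf_const(vars, rationalize(as.character(params[[tok]]), snap)))
    }
    stop("unknown identifier '", tok, "' in expression (not a variable or parameter): ", text)
  }
  out <- parseExpr()
  if (i != length(toks)) stop("trailing tokens in expression: ", text)
  out
}

#' Parse a polynomial expression
#'
#' Like [parseRationalExpression()] but requires the result to be a
#' polynomial (constant denominator).
#'
#' @inheritParams parseRationalExpression
#' @return a [QPolynomial]
#' @export
parsePolynomial <- function(text, vars, params = character(), snap = NULL) {
  rf <- parseRationalExpression(text, vars, params, snap)
  if (qpDegree(rf$den) > 0L)
    stop("expression is not polynomial (nontrivial denominator): ", text)
  rf$num
}
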