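.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
          "SER", "THR", "TRP", "TYR", "VAL")
.water_resnames <- c("TIP3", "TIP4", "HOH", "WAT", "SOL", "SPC")

#' Select atoms by a VMD-like expression
#'
#' Expressions combine the keywords `name`, `resname`, `resid`, `segid`,
#' `chain` and `element` (each followed by one or more values; `resid`
#' accepts `a:b` ranges), the bare predicates `all`, `none`, `protein`,
#' `water`, `hydrogen` and `heavy`, and the boolean operators `and`, `or`,
#' `not` with parentheses. Examples: `"segid PET and name C1 C8"`,
#' `"resid 156 and name OG"`, `"not water"`.
#'
#' An empty result is not an error; it is returned (and reported via
#' `message()`) so that callers can decide how to treat it.
#'
#' @param topology a [pet_topology()].
#' @param expression selection string.
#' @param quiet suppress the empty-selection message.
#' @return object of class `atom_selection`: list with `indices` (ascending
#'   1-based atom indices) and `expr`.
#' @export
select_atoms <- function(topology, expression, quiet = FALSE) {
  stopifnot(inherits(topology, "pet_topology"))
  mask <- .eval_selection(topology, expression)
  idx <- which(mask)
  if (length(idx) == 0 && !quiet)
    message("selection '", expression, "' matched no atoms")
  structure(list(indices = idx, expr = expression), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection: ", length(x$indices), " atoms from '", x$expr, "'\n", sep = "")
  invisible(x)
}

.sel_tokenize <- function(expression) {
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.sel_keywords <- c("name", "resname", "resid", "segid", "chain", "element")
.sel_bare <- c("all", "none", "protein", "water", "hydrogen", "heavy")
.sel_ops <- c("and", "or", "not", "(", ")")

.eval_selection <- function(topology, expression) {
  toks <- .sel_tokenize(expression)
  if (length(toks) == 0) stop("empty selection expression")
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  a <- topology$atoms
  n <- nrow(a)

  peek <- function() if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
  advance <- function() { t <- peek(); st$pos <- st$pos + 1L; t }
  fail <- function(msg) stop("selection syntax error at token ", st$pos,
                             " ('", peek(), "') in '", expression, "': ", msg)

  primitive <- function() {
    t <- tolower(peek())
    if (is.na(t)) fail("unexpected end of expression")
    if (t %in% .sel_bare) {
      advance()
      return(switch(t,
        all = rep(TRUE, n),
        none = rep(FALSE, n),
        protein = a$resname %in% .aa3,
        water = a$resname %in% .water_resnames,
        hydrogen = a$element == "H",
        heavy = a$element != "H"))
    }
    if (t %in% .sel_keywords) {
      advance()
      vals <- character(0)
      while (!is.na(peek()) &&
             !(tolower(peek()) %in% c(.sel_keywords, .sel_bare, .sel_ops))) {
        vals <- c(vals, advance())
      }
      if (length(vals) == 0) fail(paste0("keyword '", t, "' needs at least one value"))
      return(switch(t,
        name = a$name %in% vals,
        resname = a$resname %in% vals,
        segid = a$segid %in% vals,
        chain = a$chain %in% vals,
        element = toupper(a$element) %in% toupper(vals) |
                  sub("\\.$", "", toupper(a$element)) %in% toupper(vals),
        resid = {
          ids <- integer(0)
          for (v in vals) {
            if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
              rng <- as.integer(strsplit(v, ":")[[1]])
              ids <- c(ids, seq(rng[1], rng[2]))
            } else if (grepl("^-?[0-9]+$", v)) {
              ids <- c(ids, as.integer(v))
            } else fail(paste0("'", v, "' is not a resid or a:b range"))
          }
          a$resid %in% ids
        }))
    }
    fail("expected a keyword, predicate, 'not' or '('")
  }

  unary <- function() {
    t <- tolower(peek())
    if (identical(t, "not")) { advance(); return(!unary()) }
    if (identical(t, "(")) {
      advance()
      v <- or_expr()
      if (!identical(tolower(peek()), ")")) fail("expected ')'")
      advance()
      return(v)
    }
    primitive()
  }

  and_expr <- function() {
    v <- unary()
    while (identical(tolower(peek()), "and")) { advance(); v <- v & unary() }
    v
  }

  or_expr <- function() {
    v <- and_expr()
    while (identical(tolower(peek()), "or")) { advance(); v <- v | and_expr() }
    v
  }

  v <- or_expr()
  if (!is.na(peek())) fail("trailing tokens")
  v
}
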