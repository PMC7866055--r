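# Atom-selection mini-grammar:
#   primitive := name <names...> | resname <names...> | resid <i|i-j ...>
#                | water | all
#   factor    := 'not' factor | '(' expr ')' | primitive
#   term      := factor ('and' factor)*
#   expr      := term ('or' term)*
# Selections are pure functions of (topology, expression): the returned
# atom indices are deterministic and order-preserving.

tokenize_selection <- function(expression) {
  toks <- list()
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1) return(toks)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  lapply(seq_along(starts), function(i) {
    list(text = substr(expression, starts[i], starts[i] + lens[i] - 1),
         pos = starts[i])
  })
}

KEYWORDS <- c("and", "or", "not", "(", ")", "name", "resname", "resid",
              "water", "all")

#' Select atoms by expression
#'
#' Resolves a selection expression against a topology. The grammar
#' supports `name`, `resname` and `resid` primitives (the latter accepting
#' integers and `i-j` ranges), the `water` shorthand (residue name in
#' `water_resnames`), `all`, and combination with `and`/`or`/`not` and
#' parentheses. `not` binds tightest, then `and`, then `or`.
#'
#' @param topology a [topology()] object.
#' @param expression selection string, e.g.
#'   `"name CA and resid 34 82 137 181 274"`.
#' @param water_resnames residue names treated as water.
#' @return object of class `Selection`: an integer vector of atom rows
#'   (1-based, ascending) with attributes `label` (the expression) and
#'   `n`.
#' @export
select_atoms <- function(topology, expression,
                         water_resnames = DEFAULT_WATER_RESNAMES) {
  toks <- tokenize_selection(expression)
  i <- 0
  peek <- function() if (i < length(toks)) toks[[i + 1]]$text else NULL
  advance <- function() {
    i <<- i + 1
    toks[[i]]
  }
  syntax_error <- function(msg) {
    pos <- if (i < length(toks)) toks[[i + 1]]$pos else nchar(expression) + 1
    stop_pf("selection syntax error at position %d: %s", pos, msg)
  }
  take_values <- function() {
    vals <- character(0)
    while (!is.null(peek()) && !(tolower(peek()) %in% KEYWORDS)) {
      vals <- c(vals, advance()$text)
    }
    if (length(vals) == 0) syntax_error("expected one or more values")
    vals
  }
  parse_primitive <- function() {
    kw <- tolower(peek())
    if (kw == "name") {
      advance()
      topology$atom_name %in% take_values()
    } else if (kw == "resname") {
      advance()
      topology$resname %in% take_values()
    } else if (kw == "resid") {
      advance()
      vals <- take_values()
      ids <- integer(0)
      for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v) && grepl("^[0-9]+-[0-9]+$", v)) {
          rng <- as.integer(strsplit(v, "-")[[1]])
          ids <- c(ids, seq(rng[1], rng[2]))
        } else if (grepl("^-?[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else {
          syntax_error(sprintf("bad resid token '%s'", v))
        }
      }
      topology$resid %in% ids
    } else if (kw == "water") {
      advance()
      topology$resname %in% water_resnames
    } else if (kw == "all") {
      advance()
      rep(TRUE, nrow(topology))
    } else {
      syntax_error(sprintf("unexpected token '%s'", peek()))
    }
  }
  parse_factor <- function() {
    if (is.null(peek())) syntax_error("unexpected end of expression")
    kw <- tolower(peek())
    if (kw == "not") {
      advance()
      !parse_factor()
    } else if (kw == "(") {
      advance()
      e <- parse_expr()
      if (is.null(peek()) || peek() != ")") syntax_error("expected ')'")
      advance()
      e
    } else {
      parse_primitive()
    }
  }
  parse_term <- function() {
    e <- parse_factor()
    while (!is.null(peek()) && tolower(peek()) == "and") {
      advance()
      e <- e & parse_factor()
    }
    e
  }
  parse_expr <- function() {
    e <- parse_term()
    while (!is.null(peek()) && tolower(peek()) == "or") {
      advance()
      e <- e | parse_term()
    }
    e
  }
  if (length(toks) == 0) stop_pf("empty selection expression")
  mask <- parse_expr()
  if (!is.null(peek())) syntax_error(sprintf("trailing token '%s'", peek()))
  idx <- which(mask)
  if (length(idx) == 0) {
    warn_pf("selection '%s' matched no atoms", expression)
  }
  as_selection(idx, expression)
}

as_selection <- function(indices, label = "selection") {
  structure(as.integer(indices), label = label, class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat(sprintf("Selection '%s': %d atoms\n", attr(x, "label"), length(x)))
  invisible(x)
}
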