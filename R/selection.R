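#' Select atoms with a small expression language
#'
#' The grammar supports the selections the analyses need:
#'
#' * `all` — every atom; `backbone` — atoms named N, CA, C, O;
#'   `heavy` — element not hydrogen; `hydrogen` — element H; `ca` — CA atoms.
#' * `name <n1> <n2> ...`, `elem <e1> ...`, `chain <c1> ...` — membership.
#' * `resid <spec> ...` where each spec is a number or a range `a:b`/`a-b`.
#' * combinators `and`, `or`, `not` (precedence `not` > `and` > `or`) and
#'   parentheses.
#'
#' e.g. `"resid 80 and name CA"`, `"backbone"`, `"heavy and chain A"`.
#'
#' @param structure a [Structure].
#' @param expression selection string.
#' @return an `AtomSelection`: list with ordered unique `indices` (1-based
#'   atom indices) and the `descriptor` string.
#' @export
select_atoms <- function(structure, expression) {
  if (!inherits(structure, "Structure")) stop("structure must be a Structure")
  toks <- strsplit(trimws(gsub("([()])", " \\1 ", expression)),
                   "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty selection expression")
  st <- new.env()
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, structure)
  if (st$pos <= length(st$toks))
    stop("unexpected token '", st$toks[st$pos], "' in selection expression")
  structure(list(indices = which(mask), descriptor = expression),
            class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat("AtomSelection: '", x$descriptor, "' -> ", length(x$indices),
      " atoms\n", sep = "")
  invisible(x)
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }

SEL_KEYWORDS <- c("and", "or", "not", "(", ")", "all", "backbone", "heavy",
                  "hydrogen", "ca", "protein", "name", "elem", "chain", "resid")

parse_or <- function(st, s) {
  m <- parse_and(st, s)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "or") {
    sel_next(st)
    m <- m | parse_and(st, s)
  }
  m
}

parse_and <- function(st, s) {
  m <- parse_unary(st, s)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "and") {
    sel_next(st)
    m <- m & parse_unary(st, s)
  }
  m
}

parse_unary <- function(st, s) {
  t <- sel_peek(st)
  if (is.na(t)) stop("selection expression ends unexpectedly")
  if (t == "not") { sel_next(st); return(!parse_unary(st, s)) }
  if (t == "(") {
    sel_next(st)
    m <- parse_or(st, s)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")")
      stop("unbalanced parenthesis in selection expression")
    sel_next(st)
    return(m)
  }
  parse_term(st, s)
}

# arguments of name/elem/chain/resid run until the next keyword; keywords
# are recognised case-sensitively (lowercase), so atom names like "CA" or
# "N" never collide with the "ca"/"name" keywords
sel_args <- function(st) {
  args <- character(0)
  while (!is.na(sel_peek(st)) && !(sel_peek(st) %in% SEL_KEYWORDS)) {
    args <- c(args, sel_next(st))
  }
  args
}

parse_term <- function(st, s) {
  t <- sel_next(st)
  a <- s$atoms
  switch(t,
    all = , protein = rep(TRUE, nrow(a)),
    backbone = a$name %in% c("N", "CA", "C", "O"),
    heavy = toupper(a$element) != "H",
    hydrogen = toupper(a$element) == "H",
    ca = a$name == "CA",
    name = {
      v <- sel_args(st)
      if (!length(v)) stop("'name' requires at least one atom name")
      a$name %in% v
    },
    elem = {
      v <- sel_args(st)
      if (!length(v)) stop("'elem' requires at least one element symbol")
      toupper(a$element) %in% toupper(v)
    },
    chain = {
      v <- sel_args(st)
      if (!length(v)) stop("'chain' requires at least one chain id")
      a$chain %in% v
    },
    resid = {
      v <- sel_args(st)
      if (!length(v)) stop("'resid' requires at least one residue spec")
      keep <- integer(0)
      for (spec in v) {
        if (grepl("^[0-9]+$", spec)) {
          keep <- c(keep, as.integer(spec))
        } else if (grepl("^[0-9]+[:-][0-9]+$", spec)) {
          ab <- as.integer(strsplit(spec, "[:-]")[[1]])
          keep <- c(keep, seq.int(ab[1], ab[2]))
        } else stop("bad residue spec '", spec, "'")
      }
      a$resid %in% keep
    },
    stop("unknown token '", t, "' in selection expression")
  )
}
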