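#' Atom selections
#'
#' Selections are written in a small VMD-like expression language and always
#' evaluate to a deterministic, order-preserving integer index set on a
#' [structure_model()].
#'
#' Grammar:
#' \preformatted{
#'   expr    := term ("or" term)*
#'   term    := factor ("and" factor)*
#'   factor  := "not" factor | "(" expr ")" | primitive
#' }
#' Primitives: `all`, `none`, `protein`, `hetero`, `heavy`, `hydrogen`,
#' `backbone`, `sidechain`, `calpha` (alias `ca`), `sidechain-O`,
#' `chain <id ...>`, `resno <n|a:b ...>`, `resname <name ...>`,
#' `name <atom ...>`, `element <sym ...>`, `segid <label ...>`.
#' Multiple values after a keyword are OR-ed.
#'
#' @param structure a `structure_model`
#' @param expr selection string
#' @return Sorted integer vector of atom indices (possibly empty).
#' @examples
#' # select_atoms(model, "chain A and resno 347 and sidechain-O")
#' @export
select_atoms <- function(structure, expr) {
  stopifnot(inherits(structure, "structure_model"))
  mask <- .sel_eval(structure$atoms, expr)
  which(mask)
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

.sel_tokenize <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# recursive-descent evaluator over the atom table; returns a logical mask
.sel_eval <- function(atoms, expr) {
  toks <- .sel_tokenize(expr)
  if (!length(toks)) stop("empty selection expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  keywords <- c("chain", "resno", "resid", "resname", "name", "element", "segid")
  flags <- c("all", "none", "protein", "hetero", "heavy", "hydrogen",
             "backbone", "sidechain", "calpha", "ca", "sidechain-o")
  stopword <- function(t) is.na(t) || t %in% c("and", "or", "not", "(", ")") ||
    tolower(t) %in% c(keywords, flags)

  operator <- function(t) is.na(t) || t %in% c("and", "or", "not", "(", ")")
  parse_values <- function() {
    if (operator(peek())) stop("selection keyword needs at least one value")
    vals <- advance()  # first value taken verbatim ("name CA", "resname CA")
    while (!stopword(peek())) vals <- c(vals, advance())
    vals
  }
  prim <- function() {
    t <- advance()
    tl <- tolower(t)
    if (tl %in% flags) {
      return(switch(tl,
        all = rep(TRUE, nrow(atoms)),
        none = rep(FALSE, nrow(atoms)),
        protein = !atoms$is_hetero,
        hetero = atoms$is_hetero,
        heavy = !(atoms$element %in% c("H", "D")),
        hydrogen = atoms$element %in% c("H", "D"),
        backbone = !atoms$is_hetero & atoms$name %in% .BACKBONE_NAMES,
        sidechain = !atoms$is_hetero & !(atoms$name %in% .BACKBONE_NAMES),
        calpha = ,
        ca = !atoms$is_hetero & atoms$name == "CA",
        `sidechain-o` = !atoms$is_hetero & atoms$element == "O" &
          !(atoms$name %in% .BACKBONE_NAMES)))
    }
    if (tl %in% keywords) {
      vals <- parse_values()
      field <- switch(tl, chain = atoms$chain,
                      resno = , resid = atoms$resno,
                      resname = atoms$resname, name = atoms$name,
                      element = atoms$element, segid = atoms$segid)
      if (tl %in% c("resno", "resid")) {
        mask <- rep(FALSE, nrow(atoms))
        for (v in vals) {
          if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
            rng <- as.integer(strsplit(v, ":")[[1]])
            mask <- mask | (field >= min(rng) & field <= max(rng))
          } else if (grepl("^-?[0-9]+$", v)) {
            mask <- mask | field == as.integer(v)
          } else stop("malformed residue number '", v, "'")
        }
        return(mask)
      }
      return(field %in% vals)
    }
    stop("malformed selection near '", t, "'")
  }
  factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of selection expression")
    if (tolower(t) == "not") { advance(); return(!factor()) }
    if (t == "(") {
      advance()
      m <- or_expr()
      if (!identical(peek(), ")")) stop("missing ')' in selection")
      advance()
      return(m)
    }
    prim()
  }
  and_expr <- function() {
    m <- factor()
    while (identical(tolower(peek()), "and")) { advance(); m <- m & factor() }
    m
  }
  or_expr <- function() {
    m <- and_expr()
    while (identical(tolower(peek()), "or")) { advance(); m <- m | and_expr() }
    m
  }
  m <- or_expr()
  if (pos <= length(toks)) stop("malformed selection: trailing '", peek(), "'")
  m
}
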