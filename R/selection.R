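# Residue selection mini-language.
#
# Grammar (case-insensitive keywords, whitespace-separated tokens):
#   expr    := andexpr ( 'or' andexpr )*
#   andexpr := unary ( 'and' unary )*
#   unary   := 'not' unary | '(' expr ')' | primary
#   primary := 'chain' LIST | 'resid' RANGES | 'resname' LIST | 'name' LIST
#            | 'protein' | 'nucleic' | 'other' | 'all' | 'none'
#   LIST    := comma-separated identifiers (e.g. A,B)
#   RANGES  := comma-separated numbers or ranges (e.g. 326-330,340)
# 'name' selects residues containing an atom with that name. Resolution is
# deterministic; 'resid' uses author numbering.

tokenize_selection <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

parse_ranges <- function(tok, pos) {
  parts <- strsplit(tok, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
      m <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
      out <- c(out, as.integer(m[2]):as.integer(m[3]))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("selection syntax error at token ", pos,
           ": bad residue range '", p, "'", call. = FALSE)
    }
  }
  out
}

# recursive-descent parser; returns logical vector over residues
sel_parse <- function(toks, pos, structure) {
  res <- sel_or(toks, pos, structure)
  if (res$pos <= length(toks))
    stop("selection syntax error at token ", res$pos, ": unexpected '",
         toks[res$pos], "'", call. = FALSE)
  res$val
}

sel_or <- function(toks, pos, structure) {
  left <- sel_and(toks, pos, structure)
  while (left$pos <= length(toks) && tolower(toks[left$pos]) == "or") {
    right <- sel_and(toks, left$pos + 1, structure)
    left <- list(val = left$val | right$val, pos = right$pos)
  }
  left
}

sel_and <- function(toks, pos, structure) {
  left <- sel_unary(toks, pos, structure)
  while (left$pos <= length(toks) && tolower(toks[left$pos]) == "and") {
    right <- sel_unary(toks, left$pos + 1, structure)
    left <- list(val = left$val & right$val, pos = right$pos)
  }
  left
}

sel_unary <- function(toks, pos, structure) {
  if (pos > length(toks))
    stop("selection syntax error at token ", pos, ": unexpected end",
         call. = FALSE)
  tk <- tolower(toks[pos])
  if (tk == "not") {
    inner <- sel_unary(toks, pos + 1, structure)
    return(list(val = !inner$val, pos = inner$pos))
  }
  if (tk == "(") {
    inner <- sel_or(toks, pos + 1, structure)
    if (inner$pos > length(toks) || toks[inner$pos] != ")")
      stop("selection syntax error at token ", inner$pos,
           ": expected ')'", call. = FALSE)
    return(list(val = inner$val, pos = inner$pos + 1))
  }
  sel_primary(toks, pos, structure)
}

sel_primary <- function(toks, pos, structure) {
  res <- structure$residues
  tk <- tolower(toks[pos])
  arg <- function() {
    if (pos + 1 > length(toks))
      stop("selection syntax error at token ", pos + 1, ": '", toks[pos],
           "' needs an argument", call. = FALSE)
    toks[pos + 1]
  }
  switch(tk,
    protein = list(val = res$polymer == "protein", pos = pos + 1),
    nucleic = list(val = res$polymer == "nucleic", pos = pos + 1),
    other   = list(val = res$polymer == "other", pos = pos + 1),
    all     = list(val = rep(TRUE, nrow(res)), pos = pos + 1),
    none    = list(val = rep(FALSE, nrow(res)), pos = pos + 1),
    chain   = list(val = res$chain %in% strsplit(arg(), ",")[[1]],
                   pos = pos + 2),
    resid   = list(val = res$resno %in% parse_ranges(arg(), pos + 1),
                   pos = pos + 2),
    resname = list(val = toupper(res$resname) %in%
                     toupper(strsplit(arg(), ",")[[1]]), pos = pos + 2),
    name    = {
      want <- toupper(strsplit(arg(), ",")[[1]])
      hit <- unique(structure$atom$resix[toupper(structure$atom$elety) %in% want])
      list(val = seq_len(nrow(res)) %in% hit, pos = pos + 2)
    },
    stop("selection syntax error at token ", pos, ": unknown keyword '",
         toks[pos], "'", call. = FALSE)
  )
}

#' Resolve a selection expression to residue indices
#'
#' @param structure a \code{Structure}
#' @param selection expression string (see package README for the grammar),
#'   or an integer vector of residue indices (passed through after
#'   validation), or NULL for all residues.
#' @return sorted integer vector of residue indices (rows of
#'   \code{structure$residues}); may be empty.
#' @export
select_residues <- function(structure, selection) {
  n <- nrow(structure$residues)
  if (is.null(selection)) return(seq_len(n))
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > n)) stop("residue index out of range")
    return(sort(unique(idx)))
  }
  toks <- tokenize_selection(selection)
  if (!length(toks)) stop("empty selection expression")
  which(sel_parse(toks, 1, structure))
}
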