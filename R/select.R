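#' Select atoms of a topology by expression
#'
#' A small deterministic selection language over atom and residue
#' attributes. Supported predicates: \code{peptide}, \code{ligand},
#' \code{heavy}, \code{hydrogen}, \code{backbone}, \code{sidechain},
#' \code{all}, \code{chain <id>[,<id>...]}, \code{resname
#' <name>[,<name>...]}, \code{resseq <a>[:<b>][,...]} and \code{name
#' <atom>[,<atom>...]}; combined with \code{and}, \code{or}, \code{not}
#' and parentheses. The result is ordered by atom serial; an empty
#' selection is allowed.
#'
#' @param topology a [Topology-class].
#' @param expression selection text, e.g. \code{"peptide and name CA"}.
#' @return integer vector of atom indices (rows of \code{atoms(topology)}).
#' @examples
#' \dontrun{atomSelect(top, "resseq 23 and name CZ")}
#' @export
atomSelect <- function(topology, expression) {
  at <- topology@atoms
  nRes <- length(topology@residues)
  resOf <- at$resIndex
  resName <- vapply(topology@residues, function(r) r$name, "")[resOf]
  resSeq <- vapply(topology@residues, function(r) as.integer(r$seqNumber), 1L)[resOf]
  chainId <- vapply(topology@residues, function(r) r$chainId, "")[resOf]
  kind <- topology@chains$kind[match(chainId, topology@chains$id)]
  isBB <- logical(nrow(at))
  for (r in topology@residues) {
    isBB[r$backbone] <- TRUE
    # hydrogens follow the heavy-atom partition of their residue: amide and
    # cap hydrogens are main chain, everything else side chain
    hs <- r$atoms[at$isHydrogen[r$atoms]]
    isBB[hs[at$name[hs] %in% c("H", "HN1", "HN2")]] <- TRUE
  }

  toks <- tokenizeSelection(expression)
  env <- list(at = at, resName = resName, resSeq = resSeq, chainId = chainId,
              kind = kind, isBB = isBB)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$env <- env; st$expr <- expression
  mask <- parseOr(st)
  if (st$pos <= length(st$toks))
    selStop(st, sprintf("unexpected token '%s'", st$toks[[st$pos]]$text))
  which(mask)
}

tokenizeSelection <- function(expression) {
  toks <- list()
  i <- 1L; n <- nchar(expression)
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(text = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(expression, i, n),
                    regexpr("^[^()[:space:]]+", substr(expression, i, n)))
    toks[[length(toks) + 1L]] <- list(text = m, at = i)
    i <- i + nchar(m)
  }
  toks
}

selStop <- function(st, msg) {
  at <- if (st$pos <= length(st$toks)) st$toks[[st$pos]]$at else nchar(st$expr) + 1L
  stop(sprintf("atomSelect: %s at position %d in '%s'", msg, at, st$expr),
       call. = FALSE)
}

peekTok <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]]$text else NULL
takeTok <- function(st) { t <- peekTok(st); st$pos <- st$pos + 1L; t }

parseOr <- function(st) {
  m <- parseAnd(st)
  while (identical(peekTok(st), "or")) { takeTok(st); m <- m | parseAnd(st) }
  m
}

parseAnd <- function(st) {
  m <- parseUnary(st)
  while (identical(peekTok(st), "and")) { takeTok(st); m <- m & parseUnary(st) }
  m
}

parseUnary <- function(st) {
  t <- peekTok(st)
  if (is.null(t)) selStop(st, "expected a predicate")
  if (t == "not") { takeTok(st); return(!parseUnary(st)) }
  if (t == "(") {
    takeTok(st)
    m <- parseOr(st)
    if (!identical(peekTok(st), ")")) selStop(st, "expected ')'")
    takeTok(st)
    return(m)
  }
  parsePredicate(st)
}

parsePredicate <- function(st) {
  env <- st$env
  t <- takeTok(st)
  argOf <- function() {
    a <- peekTok(st)
    if (is.null(a) || a %in% c("and", "or", "not", "(", ")"))
      selStop(st, sprintf("predicate '%s' needs an argument", t))
    takeTok(st)
  }
  switch(t,
    peptide = env$kind == "peptide",
    ligand = env$kind == "ligand",
    heavy = !env$at$isHydrogen,
    hydrogen = env$at$isHydrogen,
    backbone = env$isBB,
    sidechain = !env$isBB,
    all = rep(TRUE, nrow(env$at)),
    chain = env$chainId %in% strsplit(argOf(), ",")[[1]],
    resname = env$resName %in% strsplit(argOf(), ",")[[1]],
    name = env$at$name %in% strsplit(argOf(), ",")[[1]],
    resseq = {
      parts <- strsplit(argOf(), ",")[[1]]
      keep <- rep(FALSE, nrow(env$at))
      for (p in parts) {
        r <- as.integer(strsplit(p, "[:\\-]")[[1]])
        if (any(is.na(r)) || length(r) > 2) {
          st$pos <- st$pos - 1L
          selStop(st, sprintf("malformed residue range '%s'", p))
        }
        keep <- keep | (env$resSeq >= r[1] & env$resSeq <= r[length(r)])
      }
      keep
    },
    { st$pos <- st$pos - 1L; selStop(st, sprintf("unknown predicate '%s'", t)) })
}
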