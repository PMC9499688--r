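# Residue templates: idealized geometry plus role annotations (backbone /
# side-chain partition, H-bond donors and acceptors, aromatic rings, methyl
# carbons). Shipped as a plain-text table; users may supply the same format
# for additional residues.

templateCache <- new.env(parent = emptyenv())

#' Read a residue template table
#'
#' The plain-text format is block-oriented: each residue starts with
#' \code{RES <name> <kind>} (kind one of \code{peptide}, \code{cap},
#' \code{ligand}) and contains \code{ATOM <name> <element> <MC|SC> <x> <y>
#' <z>} rows (idealized coordinates in nm), an \code{ANCHOR} row naming the
#' three atoms used to graft the template onto built coordinates, and
#' optional \code{DONOR <heavy> <hydrogen>}, \code{ACCEPTOR <atom>},
#' \code{RING <a,b,c,...>} and \code{METHYL <atom>} annotation rows.
#'
#' @param path template file.
#' @return named list of template records.
#' @seealso [defaultTemplates()]
#' @export
readTemplates <- function(path) {
  if (!file.exists(path)) stop("readTemplates: no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (is.null(cur)) return(out)
    cur$atoms <- do.call(rbind, cur$atomRows)
    cur$atomRows <- NULL
    out[[cur$name]] <- cur
    out
  }
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (key == "RES") {
      out <- flush(cur, out)
      cur <- list(name = tok[2], kind = tok[3], atomRows = list(),
                  anchors = character(), donors = NULL,
                  acceptors = character(), rings = list(), methyls = character())
    } else if (is.null(cur)) {
      stop("readTemplates: record before any RES line: ", ln)
    } else if (key == "ATOM") {
      cur$atomRows[[length(cur$atomRows) + 1L]] <- data.frame(
        name = tok[2], element = tok[3], part = tok[4],
        x = as.numeric(tok[5]), y = as.numeric(tok[6]), z = as.numeric(tok[7]),
        stringsAsFactors = FALSE)
    } else if (key == "ANCHOR") {
      cur$anchors <- tok[-1]
    } else if (key == "DONOR") {
      cur$donors <- rbind(cur$donors, tok[2:3])
    } else if (key == "ACCEPTOR") {
      cur$acceptors <- c(cur$acceptors, tok[2])
    } else if (key == "RING") {
      cur$rings <- c(cur$rings, list(strsplit(tok[2], ",")[[1]]))
    } else if (key == "METHYL") {
      cur$methyls <- c(cur$methyls, tok[2])
    } else {
      stop("readTemplates: unknown record '", key, "'")
    }
  }
  out <- flush(cur, out)
  for (nm in names(out)) {
    tpl <- out[[nm]]
    known <- tpl$atoms$name
    refd <- c(tpl$anchors, as.vector(tpl$donors), tpl$acceptors,
              unlist(tpl$rings), tpl$methyls)
    bad <- setdiff(refd, known)
    if (length(bad))
      stop(sprintf("readTemplates: residue %s references unknown atoms: %s",
                   nm, paste(bad, collapse = ", ")))
  }
  out
}

#' Packaged residue templates
#'
#' Templates for the residues of the hIAPP(20-29) study system: SER, ASN,
#' PHE, GLY, ALA, ILE, LEU, the ACE/NH2 terminal caps, and the MEL
#' (melatonin) ligand. Other residues can be supplied via
#' [readTemplates()].
#'
#' @return named list of template records.
#' @export
defaultTemplates <- function() {
  if (!is.null(templateCache$default)) return(templateCache$default)
  path <- system.file("extdata", "residue_templates.txt", package = "oligolens")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "residue_templates.txt")
  tpl <- readTemplates(path)
  templateCache$default <- tpl
  tpl
}

elementMass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  out <- m[element]
  if (any(is.na(out)))
    stop("elementMass: unknown element(s): ",
         paste(unique(element[is.na(out)]), collapse = ", "))
  as.numeric(out)
}

# Bondi van der Waals radii in nm; hydrogens are excluded from contact and
# surface analyses, so their radius is NA by convention.
elementVdw <- function(element) {
  r <- c(H = NA_real_, C = 0.170, N = 0.155, O = 0.152, S = 0.180)
  out <- r[element]
  if (any(is.na(out) & element != "H"))
    stop("elementVdw: unknown element(s): ",
         paste(unique(element[is.na(out) & element != "H"]), collapse = ", "))
  as.numeric(out)
}

threeLetter <- function(oneLetter) {
  map <- c(A = "ALA", G = "GLY", S = "SER", N = "ASN", F = "PHE",
           I = "ILE", L = "LEU", V = "VAL", T = "THR", C = "CYS",
           M = "MET", P = "PRO", D = "ASP", E = "GLU", Q = "GLN",
           K = "LYS", R = "ARG", H = "HIS", W = "TRP", Y = "TYR")
  out <- map[strsplit(oneLetter, "")[[1]]]
  if (any(is.na(out)))
    stop("unknown residue letter(s): ",
         paste(strsplit(oneLetter, "")[[1]][is.na(out)], collapse = ", "))
  as.character(out)
}

# Build a residue record (list form used by Topology@residues) from a
# template, given atom rows already appended to an atoms table.
residueRecordFromTemplate <- function(tpl, atomIdx, atomNames, chainId, seqNumber,
                                      isHydrogen) {
  lookup <- function(nms) {
    i <- atomIdx[match(nms, atomNames)]
    if (any(is.na(i))) NA_integer_ else i
  }
  present <- function(nms) all(nms %in% atomNames)
  donors <- NULL
  if (!is.null(tpl$donors)) {
    for (k in seq_len(nrow(tpl$donors))) {
      pair <- tpl$donors[k, ]
      if (present(pair)) {
        donors <- rbind(donors, c(lookup(pair[1]), lookup(pair[2])))
      } else if (pair[1] %in% atomNames) {
        if (pair[1] == "N" && pair[2] == "H") {
          # backbone amide hydrogen: reconstructable downstream, keep donor
          donors <- rbind(donors, c(lookup(pair[1]), NA_integer_))
        } else {
          warning(sprintf("residue %s %s: donor %s lacks hydrogen %s; donor disabled",
                          tpl$name, chainId, pair[1], pair[2]), call. = FALSE)
        }
      }
    }
  }
  if (!is.null(donors)) storage.mode(donors) <- "integer"
  heavy <- atomIdx[!isHydrogen]
  heavyNames <- atomNames[!isHydrogen]
  mcNames <- tpl$atoms$name[tpl$atoms$part == "MC"]
  backbone <- heavy[heavyNames %in% mcNames]
  sidechain <- setdiff(heavy, backbone)
  rings <- lapply(tpl$rings, function(r) {
    if (!present(r)) return(NULL)
    vapply(r, function(a) lookup(a), 1L)
  })
  rings <- rings[!vapply(rings, is.null, TRUE)]
  list(name = tpl$name, chainId = chainId, seqNumber = seqNumber,
       atoms = atomIdx, backbone = backbone, sidechain = sidechain,
       donors = donors,
       acceptors = unname(vapply(tpl$acceptors[tpl$acceptors %in% atomNames],
                                 lookup, 1L)),
       rings = rings,
       methyls = unname(vapply(tpl$methyls[tpl$methyls %in% atomNames],
                               lookup, 1L)))
}
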