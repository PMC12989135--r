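#' @importFrom stats rnorm runif setNames sd cor
#' @importFrom utils head tail read.delim
NULL

STANDARD_AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

IG_ROLES <- c("ig_heavy", "ig_light", "nanobody", "scfv", "tcr_alpha", "tcr_beta")
AG_ROLES <- c("antigen", "mhc", "peptide")

role_side <- function(role) {
  ifelse(role %in% IG_ROLES, "ig", ifelse(role %in% AG_ROLES, "ag", NA_character_))
}

# Node-type class used by the auxiliary node head: antigen / heavy / light.
role_node_type <- function(role) {
  if (role %in% c("ig_heavy", "nanobody", "scfv", "tcr_alpha")) return("heavy")
  if (role %in% c("ig_light", "tcr_beta")) return("light")
  "antigen"
}

#' Construct a complex structure object
#'
#' A `complex_structure` holds an ordered set of chains, each an ordered list
#' of residues; every residue carries its atom table (name, element, x/y/z in
#' Angstrom, occupancy, altloc, HETATM flag) and its author residue number
#' (with insertion code) as the stable `seq_index` key.
#'
#' @param chains named list, chain id to list of residues.
#' @param source_id free-text identifier for provenance.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(chains, source_id = "") {
  stopifnot(is.list(chains), length(names(chains)) == length(chains))
  if (anyDuplicated(names(chains))) stop("chain ids must be unique")
  structure(list(chains = chains, source_id = source_id),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  nres <- vapply(x$chains, length, integer(1))
  cat("<complex_structure> ", x$source_id, "\n", sep = "")
  cat("  chains:", paste0(names(x$chains), " (", nres, " res)", collapse = ", "), "\n")
  invisible(x)
}

n_residues <- function(s) sum(vapply(s$chains, length, integer(1)))

n_atoms <- function(s) {
  sum(vapply(s$chains, function(ch) {
    sum(vapply(ch, function(r) nrow(r$atoms), integer(1)))
  }, integer(1)))
}

new_residue <- function(name3, seq_index, atoms) {
  list(name3 = name3, seq_index = seq_index, atoms = atoms)
}

#' Parse an Ig-Ag complex structure from PDB or mmCIF
#'
#' Reads all ATOM/HETATM records, preserving altloc labels and occupancies,
#' and groups residues per chain in file order. Coordinates are in Angstrom.
#'
#' @param path file path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @return A [complex_structure()].
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) stop("cannot parse ", format, " file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in ", path)
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy[is.na(at$elesy)] <- ""
  element <- ifelse(at$elesy == "",
                    toupper(substr(gsub("[0-9]", "", at$elety), 1L, 1L)),
                    toupper(at$elesy))

  # residues change whenever chain/resno/insert changes, in file order
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  brk <- c(TRUE, key[-1L] != key[-length(key)])
  res_id <- cumsum(brk)

  chains <- list()
  for (ridx in split(seq_len(nrow(at)), res_id)) {
    first <- ridx[1L]
    cid <- at$chain[first]
    seq_index <- paste0(at$resno[first], at$insert[first])
    atoms <- data.frame(
      name = at$elety[ridx],
      element = element[ridx],
      x = at$x[ridx], y = at$y[ridx], z = at$z[ridx],
      occupancy = at$o[ridx],
      altloc = at$alt[ridx],
      is_hetatm = at$type[ridx] == "HETATM",
      stringsAsFactors = FALSE
    )
    if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
      stop("non-finite coordinates in residue ", seq_index, " chain ", cid)
    }
    res <- new_residue(at$resid[first], seq_index, atoms)
    if (is.null(chains[[cid]])) chains[[cid]] <- list()
    chains[[cid]][[length(chains[[cid]]) + 1L]] <- res
  }
  complex_structure(chains, source_id = basename(path))
}

#' Clean a parsed structure
#'
#' Applies the standard curation rules: residues with HETATM records or a
#' non-standard residue name are removed; where a residue has alternative
#' locations, only the altloc label with the highest summed occupancy is
#' retained (ties broken by file order) and altloc flags are cleared. Chains
#' emptied by cleaning are dropped. Coordinates of retained atoms are never
#' modified, so cleaning is idempotent.
#'
#' @param s a [complex_structure()].
#' @return A cleaned [complex_structure()].
#' @export
clean_structure <- function(s) {
  stopifnot(inherits(s, "complex_structure"))
  chains <- lapply(s$chains, function(ch) {
    kept <- lapply(ch, clean_residue)
    kept[!vapply(kept, is.null, logical(1))]
  })
  chains <- chains[vapply(chains, length, integer(1)) > 0L]
  if (length(chains) == 0L) stop("no standard residues remain after cleaning")
  complex_structure(chains, source_id = s$source_id)
}

clean_residue <- function(r) {
  if (any(r$atoms$is_hetatm)) return(NULL)
  if (!(r$name3 %in% STANDARD_AA3)) return(NULL)
  a <- r$atoms
  alts <- unique(a$altloc[a$altloc != ""])
  if (length(alts) > 0L) {
    occ <- vapply(alts, function(al) sum(a$occupancy[a$altloc == al]), numeric(1))
    best <- alts[which.max(occ)]  # which.max keeps first on ties (file order)
    a <- a[a$altloc == "" | a$altloc == best, , drop = FALSE]
    a$altloc <- ""
    rownames(a) <- NULL
  }
  if (nrow(a) == 0L) return(NULL)
  new_residue(r$name3, r$seq_index, a)
}

#' Read a chain annotation table
#'
#' Accepts TSV (columns `chain_id`, `role`, `cdr_intervals`) or JSON (an array
#' of objects with those fields). `cdr_intervals` is a semicolon-separated
#' list of inclusive author-numbered ranges, e.g. `"26-32;52-56"`; empty for
#' antigen-side chains.
#'
#' @param path annotation file path.
#' @return A data frame with columns `chain_id`, `role`, `cdr_intervals`.
#' @export
read_chain_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  if (!all(c("chain_id", "role") %in% names(df))) {
    stop("annotation must have columns chain_id and role")
  }
  if (is.null(df$cdr_intervals)) df$cdr_intervals <- ""
  df$cdr_intervals[is.na(df$cdr_intervals)] <- ""
  df[, c("chain_id", "role", "cdr_intervals")]
}

parse_cdr_intervals <- function(txt) {
  if (is.na(txt) || txt == "") return(matrix(numeric(0), ncol = 2L))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*(-?\\d+)\\s*-\\s*(-?\\d+)\\s*$", p))[[1]]
    if (length(m) != 3L) stop("bad CDR interval: '", p, "'")
    as.numeric(m[2:3])
  }, numeric(2)))
  if (any(iv[, 1] > iv[, 2])) stop("CDR interval start > end")
  iv
}

#' Assign Ig/Ag roles to the chains of a complex
#'
#' Builds a `typed_complex`: every chain gets a role from the controlled
#' vocabulary (`ig_heavy`, `ig_light`, `nanobody`, `scfv`, `tcr_alpha`,
#' `tcr_beta` on the Ig side; `antigen`, `mhc`, `peptide` on the antigen
#' side), and CDR intervals (author numbering, inclusive) are resolved to
#' per-residue masks.
#'
#' @param s a cleaned [complex_structure()].
#' @param ann annotation data frame (see [read_chain_annotation()]) or a path
#'   to an annotation file.
#' @return An object of class `typed_complex` with fields `structure` and
#'   `annotations`.
#' @export
assign_roles <- function(s, ann) {
  stopifnot(inherits(s, "complex_structure"))
  if (is.character(ann) && length(ann) == 1L) ann <- read_chain_annotation(ann)
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (is.null(ann$cdr_intervals)) ann$cdr_intervals <- ""
  ann$cdr_intervals[is.na(ann$cdr_intervals)] <- ""
  missing <- setdiff(names(s$chains), ann$chain_id)
  if (length(missing) > 0L) {
    stop("unannotated chain(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(ann$role, c(IG_ROLES, AG_ROLES))
  if (length(bad) > 0L) stop("unknown role(s): ", paste(bad, collapse = ", "))

  annotations <- lapply(names(s$chains), function(cid) {
    row <- ann[match(cid, ann$chain_id), ]
    side <- role_side(row$role)
    iv <- parse_cdr_intervals(row$cdr_intervals)
    if (nrow(iv) > 0L && side != "ig") {
      stop("CDR intervals given for non-Ig chain ", cid)
    }
    if (nrow(iv) > 1L) {
      o <- order(iv[, 1])
      iv <- iv[o, , drop = FALSE]
      if (any(iv[-1L, 1] <= iv[-nrow(iv), 2])) {
        stop("overlapping CDR intervals on chain ", cid)
      }
    }
    resno <- vapply(s$chains[[cid]], function(r) {
      as.numeric(sub("[A-Za-z]+$", "", r$seq_index))
    }, numeric(1))
    cdr_mask <- rep(FALSE, length(resno))
    for (k in seq_len(nrow(iv))) {
      if (iv[k, 1] < min(resno) || iv[k, 2] > max(resno)) {
        stop("CDR interval ", iv[k, 1], "-", iv[k, 2],
             " outside chain ", cid, " numbering range")
      }
      cdr_mask <- cdr_mask | (resno >= iv[k, 1] & resno <= iv[k, 2])
    }
    list(chain_id = cid, role = row$role, side = side,
         cdr_intervals = iv, cdr_mask = cdr_mask)
  })
  sides <- vapply(annotations, `[[`, character(1), "side")
  if (!("ig" %in% sides) || !("ag" %in% sides)) {
    stop("no interface possible: need at least one Ig-side and one Ag-side chain")
  }
  structure(list(structure = s, annotations = annotations),
            class = "typed_complex")
}

#' @export
print.typed_complex <- function(x, ...) {
  cat("<typed_complex> ", x$structure$source_id, "\n", sep = "")
  for (a in x$annotations) {
    cat("  ", a$chain_id, ": ", a$role, " (", a$side, "), ",
        sum(a$cdr_mask), " CDR residues\n", sep = "")
  }
  invisible(x)
}

#' Write a complex structure as PDB
#'
#' @param s a [complex_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "complex_structure"))
  rows <- list()
  for (cid in names(s$chains)) {
    for (r in s$chains[[cid]]) {
      ins <- sub("^-?\\d+", "", r$seq_index)
      num <- as.integer(sub("[A-Za-z]+$", "", r$seq_index))
      a <- r$atoms
      rows[[length(rows) + 1L]] <- data.frame(
        type = ifelse(a$is_hetatm, "HETATM", "ATOM"),
        elety = a$name, resid = r$name3, chain = cid,
        resno = num, insert = ins, x = a$x, y = a$y, z = a$z,
        o = a$occupancy, alt = a$altloc, elesy = a$element,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  xyz <- as.numeric(t(as.matrix(df[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = df$type, resno = df$resno,
    resid = df$resid, eleno = seq_len(nrow(df)), elety = df$elety,
    chain = df$chain, insert = ifelse(df$insert == "", NA, df$insert),
    alt = ifelse(df$alt == "", NA, df$alt), o = df$o,
    b = rep(0, nrow(df)), elesy = df$elesy
  )
  invisible(path)
}

# One-letter sequence of a chain (unknown residues -> X).
chain_sequence <- function(residues) {
  v <- vapply(residues, function(r) {
    s <- AA3_TO_1[r$name3]
    if (is.na(s)) "X" else s
  }, character(1))
  paste0(v, collapse = "")
}

# Flat residue table for a typed complex: chain, position, key, side, role.
residue_table <- function(tc) {
  out <- list()
  for (a in tc$annotations) {
    ch <- tc$structure$chains[[a$chain_id]]
    out[[a$chain_id]] <- data.frame(
      chain = a$chain_id,
      pos = seq_along(ch),
      key = paste0(a$chain_id, ":", vapply(ch, `[[`, character(1), "seq_index")),
      name3 = vapply(ch, `[[`, character(1), "name3"),
      side = a$side,
      role = a$role,
      node_type = role_node_type(a$role),
      is_cdr = a$cdr_mask,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
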