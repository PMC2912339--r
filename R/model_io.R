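# Core containers: topology (atom metadata), trajectory (topology + frames),
# selection (ordered atom index subset).  Coordinates are stored bio3d-style
# as an M x 3N matrix (frames in rows, atom coordinates interleaved
# x1,y1,z1,x2,...), which keeps the covariance machinery a plain crossprod.

#' Construct a topology
#'
#' A topology holds the per-atom metadata shared by every frame of a
#' trajectory: PDB-style identifiers, a molecule label used by the selection
#' language (`protein`, `guide-RNA`, `target-RNA`, `water`, `ion`, ...) and
#' optional force-field parameters (partial charge, Lennard-Jones sigma and
#' epsilon, intrinsic Born radius, van der Waals radius, mass).
#'
#' @param atoms data.frame with at least columns `name`, `resname`, `resid`,
#'   `chain`; optional `serial`, `element`, `occupancy`, `b`, `molecule`,
#'   `charge`, `lj_sigma`, `lj_epsilon`, `born_radius`, `vdw_radius`, `mass`.
#' @return object of class `topology`.
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("topology: missing atom columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (anyDuplicated(atoms$serial))
    stop("topology: atom serials must be unique")
  if (any(atoms$resid < 1))
    stop("topology: residue ids must be >= 1 (PDB numbering)")
  if (is.null(atoms$element)) atoms$element <- substr(trimws(atoms$name), 1, 1)
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$molecule)) atoms$molecule <- "protein"
  for (col in c("charge", "lj_sigma", "lj_epsilon", "born_radius",
                "vdw_radius", "mass"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (any(!is.na(atoms$mass) & atoms$mass <= 0))
    stop("topology: masses must be positive")
  if (any(!is.na(atoms$vdw_radius) & atoms$vdw_radius <= 0))
    stop("topology: van der Waals radii must be positive")
  structure(list(atoms = atoms, n_atoms = n), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      "molecules:", paste(unique(x$atoms$molecule), collapse = "/"), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param top a [topology()].
#' @param xyz M x 3N coordinate matrix (Angstrom; frames in rows) or a list
#'   of N x 3 matrices.
#' @param times per-frame times in ps (strictly increasing). Defaults to
#'   `0, time_step, ...`.
#' @param time_step frame spacing in ps (default 2, the conventional analysis
#'   stride for snapshots saved every 2 ps).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(top, xyz, times = NULL, time_step = 2) {
  stopifnot(inherits(top, "topology"))
  if (is.list(xyz) && !is.matrix(xyz))
    xyz <- do.call(rbind, lapply(xyz, function(m) as.numeric(t(m))))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * top$n_atoms)
    stop("trajectory: each frame must supply ", top$n_atoms,
         " atom coordinates (got ", ncol(xyz) / 3, ")")
  if (!all(is.finite(xyz)))
    stop("trajectory: coordinates must be finite")
  m <- nrow(xyz)
  if (is.null(times)) times <- (seq_len(m) - 1) * time_step
  if (length(times) != m || any(diff(times) <= 0) && m > 1)
    stop("trajectory: frame_times must be strictly increasing, one per frame")
  structure(list(top = top, xyz = xyz, times = as.numeric(times),
                 time_step = time_step),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", x$top$n_atoms, "atoms (",
      x$times[1], "-", x$times[n_frames(x)], "ps )\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @param sel optional [select()] result restricting the atoms.
#' @export
frame_coords <- function(traj, i, sel = NULL) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  if (!is.null(sel)) m <- m[sel$indices, , drop = FALSE]
  m
}

# column indices into the flat 3N layout for an atom index vector
.xyz_cols <- function(idx) {
  as.numeric(t(outer(3 * (idx - 1), 1:3, "+")))
}

#' Subset a trajectory's coordinate matrix to a selection
#' @return M x 3n matrix for the selected atoms.
#' @keywords internal
sel_xyz <- function(traj, sel) traj$xyz[, .xyz_cols(sel$indices), drop = FALSE]

## ---------------------------------------------------------------- selections

#' Select atoms with a small expression language
#'
#' Supported terms: `name <names...>`, `resname <names...>`,
#' `resid <ranges...>` (each range `N` or `N-M`), `chain <ids...>`,
#' `molecule <labels...>`.  Terms combine with `and` / `or` (with `and`
#' binding tighter) and parentheses.  Matching is order-preserving and
#' deterministic; an empty result is legal.
#'
#' @param top a [topology()].
#' @param expr selection expression, e.g. `"name CA and resid 20-100"`.
#' @param label optional label stored on the selection.
#' @return object of class `selection` with an ordered `indices` vector.
#' @examples
#' top <- topology(data.frame(name = "CA", resname = "ALA",
#'                            resid = 1:10, chain = "A"))
#' select(top, "resid 2-4 or resid 8")$indices
#' @export
select <- function(top, expr, label = expr) {
  stopifnot(inherits(top, "topology"), is.character(expr), length(expr) == 1)
  toks <- .sel_tokenize(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .sel_parse_or(st, top)
  if (st$pos <= length(st$toks))
    stop("select: trailing tokens in expression near '",
         st$toks[st$pos], "'")
  structure(list(indices = which(mask), label = label), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

.sel_tokenize <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0) stop("select: empty expression")
  toks
}

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA

.sel_next <- function(st) {
  t <- .sel_peek(st)
  st$pos <- st$pos + 1L
  t
}

.sel_parse_or <- function(st, top) {
  mask <- .sel_parse_and(st, top)
  while (identical(.sel_peek(st), "or")) {
    .sel_next(st)
    mask <- mask | .sel_parse_and(st, top)
  }
  mask
}

.sel_parse_and <- function(st, top) {
  mask <- .sel_parse_primary(st, top)
  while (identical(.sel_peek(st), "and")) {
    .sel_next(st)
    mask <- mask & .sel_parse_primary(st, top)
  }
  mask
}

.sel_keywords <- c("name", "resname", "resid", "chain", "molecule")

.sel_parse_primary <- function(st, top) {
  t <- .sel_next(st)
  if (is.na(t)) stop("select: unexpected end of expression")
  if (t == "(") {
    mask <- .sel_parse_or(st, top)
    if (!identical(.sel_next(st), ")"))
      stop("select: unbalanced parenthesis")
    return(mask)
  }
  if (!(t %in% .sel_keywords))
    stop("select: malformed expression, expected a keyword (",
         paste(.sel_keywords, collapse = "/"), ") but found '", t, "'")
  vals <- character(0)
  while (!is.na(.sel_peek(st)) &&
         !(.sel_peek(st) %in% c(.sel_keywords, "and", "or", "(", ")")))
    vals <- c(vals, .sel_next(st))
  if (length(vals) == 0)
    stop("select: keyword '", t, "' requires at least one value")
  at <- top$atoms
  switch(t,
    name     = trimws(at$name) %in% vals,
    resname  = trimws(at$resname) %in% vals,
    chain    = trimws(at$chain) %in% vals,
    molecule = at$molecule %in% vals,
    resid    = {
      mask <- rep(FALSE, nrow(at))
      for (v in vals) {
        if (grepl("^[0-9]+-[0-9]+$", v)) {
          rng <- as.integer(strsplit(v, "-")[[1]])
          mask <- mask | (at$resid >= rng[1] & at$resid <= rng[2])
        } else if (grepl("^[0-9]+$", v)) {
          mask <- mask | (at$resid == as.integer(v))
        } else stop("select: bad resid value '", v, "'")
      }
      mask
    })
}

## ---------------------------------------------------------------- structure IO

#' Read a structure or trajectory file
#'
#' Two dialects are understood.  `pdb-multimodel` parses fixed-width
#' ATOM/HETATM records, with every MODEL/ENDMDL block becoming one frame
#' (a file without MODEL records yields a single frame); atom metadata comes
#' from the first model, residue numbering stays 1-based as printed, the
#' first alternate location is kept and insertion codes are rejected.
#' `frame-dump` is the package's documented plain-text trajectory format
#' (see [write_structure()]): a `TRAJDUMP` header with the atom count,
#' an optional atom table, then per-frame blocks of N x/y/z rows.
#'
#' @param path file path.
#' @param dialect `"pdb-multimodel"` or `"frame-dump"`.
#' @return a [trajectory()].
#' @export
read_structure <- function(path, dialect = c("pdb-multimodel", "frame-dump")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  lines <- readLines(path)
  if (dialect == "pdb-multimodel") .read_pdb_multimodel(lines, path)
  else .read_frame_dump(lines, path)
}

.num_field <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(v))
    stop("read_structure: unparsable ", what, " field at line ", lineno,
         " ('", trimws(s), "')")
  v
}

.read_pdb_multimodel <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("read_structure: no ATOM/HETATM records in ", path)
  model_starts <- grep("^MODEL", lines)
  # frame id per line: 0 before any MODEL (promoted to 1 if no MODEL at all)
  frame_of <- findInterval(seq_along(lines), model_starts)
  if (length(model_starts) == 0) frame_of <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  frames_id <- frame_of[atom_lines]
  if (any(frames_id == 0))
    stop("read_structure: ATOM records before first MODEL in ", path)
  nmod <- max(frames_id)

  parse_block <- function(lns, linenos, first) {
    n <- length(lns)
    x <- y <- z <- numeric(n)
    for (k in seq_len(n)) {
      x[k] <- .num_field(substr(lns[k], 31, 38), linenos[k], "x coordinate")
      y[k] <- .num_field(substr(lns[k], 39, 46), linenos[k], "y coordinate")
      z[k] <- .num_field(substr(lns[k], 47, 54), linenos[k], "z coordinate")
    }
    if (!first) return(cbind(x, y, z))
    icode <- trimws(substr(lns, 27, 27))
    if (any(icode != ""))
      stop("read_structure: insertion codes are not supported (line ",
           linenos[which(icode != "")[1]], ")")
    altloc <- trimws(substr(lns, 17, 17))
    keep <- altloc == "" | altloc == "A" |
      !duplicated(paste(substr(lns, 13, 16), substr(lns, 18, 26)))
    occ <- suppressWarnings(as.numeric(substr(lns, 55, 60)))
    bfac <- suppressWarnings(as.numeric(substr(lns, 61, 66)))
    atoms <- data.frame(
      serial = as.integer(substr(lns, 7, 11)),
      name = trimws(substr(lns, 13, 16)),
      resname = trimws(substr(lns, 18, 20)),
      chain = trimws(substr(lns, 22, 22)),
      resid = as.integer(substr(lns, 23, 26)),
      occupancy = ifelse(is.na(occ), 1, occ),
      b = ifelse(is.na(bfac), 0, bfac),
      element = trimws(substr(lns, 77, 78)),
      stringsAsFactors = FALSE)
    atoms$chain[atoms$chain == ""] <- "A"
    atoms$element[atoms$element == ""] <-
      substr(gsub("[0-9]", "", atoms$name[atoms$element == ""]), 1, 1)
    atoms$molecule <- .guess_molecule(atoms)
    list(atoms = atoms[keep, , drop = FALSE], xyz = cbind(x, y, z)[keep, ,
         drop = FALSE], keep = keep)
  }

  first_idx <- atom_lines[frames_id == 1]
  first <- parse_block(lines[first_idx], first_idx, TRUE)
  n <- nrow(first$atoms)
  top <- topology(first$atoms)
  xyz <- matrix(NA_real_, nrow = nmod, ncol = 3 * n)
  xyz[1, ] <- as.numeric(t(first$xyz))
  if (nmod > 1) {
    for (mdl in 2:nmod) {
      idx <- atom_lines[frames_id == mdl]
      if (length(idx) != length(first_idx))
        stop("read_structure: model ", mdl, " has ", length(idx),
             " atoms but model 1 has ", length(first_idx))
      blk <- parse_block(lines[idx], idx, FALSE)
      xyz[mdl, ] <- as.numeric(t(blk[first$keep, , drop = FALSE]))
    }
  }
  trajectory(top, xyz)
}

.guess_molecule <- function(atoms) {
  rn <- trimws(atoms$resname)
  mol <- rep("protein", nrow(atoms))
  mol[rn %in% c("HOH", "WAT", "SOL", "TIP3")] <- "water"
  mol[rn %in% c("MG", "NA", "CL", "K", "ZN", "CA2", "MN")] <- "ion"
  mol[rn %in% c("A", "U", "G", "C", "RA", "RU", "RG", "RC")] <- "guide-RNA"
  mol
}

.read_frame_dump <- function(lines, path) {
  if (length(lines) < 2 || !grepl("^TRAJDUMP", lines[1]))
    stop("read_structure: ", path, " is not a TRAJDUMP frame-dump file")
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (hdr[1] != "NATOMS")
    stop("read_structure: frame-dump missing NATOMS header at line 2")
  n <- as.integer(hdr[2])
  i <- 3L
  atoms <- NULL
  atom_rows <- list()
  while (i <= length(lines) && grepl("^ATOM\\b", lines[i])) {
    atom_rows[[length(atom_rows) + 1L]] <- strsplit(trimws(lines[i]),
                                                    "\\s+")[[1]]
    i <- i + 1L
  }
  if (length(atom_rows) > 0) {
    if (length(atom_rows) != n)
      stop("read_structure: frame-dump atom table has ", length(atom_rows),
           " rows, expected ", n)
    m <- do.call(rbind, atom_rows)
    atoms <- data.frame(serial = as.integer(m[, 2]), name = m[, 3],
                        resname = m[, 4], resid = as.integer(m[, 5]),
                        chain = m[, 6], molecule = m[, 7],
                        stringsAsFactors = FALSE)
  } else {
    atoms <- data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
                        resid = seq_len(n), chain = "A",
                        molecule = "protein", stringsAsFactors = FALSE)
  }
  top <- topology(atoms)
  frames <- list()
  times <- numeric(0)
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] != "FRAME")
      stop("read_structure: expected FRAME record at line ", i)
    t_ps <- .num_field(f[2], i, "frame time")
    if (i + n > length(lines))
      stop("read_structure: truncated frame block starting at line ", i)
    co <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      v <- strsplit(trimws(lines[i + k]), "\\s+")[[1]]
      if (length(v) != 3)
        stop("read_structure: expected 3 coordinates at line ", i + k)
      co[k, ] <- vapply(seq_len(3), function(j)
        .num_field(v[j], i + k, "coordinate"), numeric(1))
    }
    frames[[length(frames) + 1L]] <- co
    times <- c(times, t_ps)
    i <- i + n + 1L
  }
  if (length(frames) == 0)
    stop("read_structure: frame-dump has no frames")
  trajectory(top, frames, times = times,
             time_step = if (length(times) > 1) diff(times)[1] else 2)
}

#' Write a trajectory to disk
#'
#' `pdb-multimodel` writes standard fixed-width ATOM records wrapped in
#' MODEL/ENDMDL blocks (coordinates at the format's 3-decimal precision).
#' `frame-dump` writes the package's plain-text trajectory dialect:
#' ```
#' TRAJDUMP v1
#' NATOMS <n>
#' ATOM <serial> <name> <resname> <resid> <chain> <molecule>   (n rows)
#' FRAME <time ps>
#' <x> <y> <z>                                                 (n rows)
#' ...
#' ```
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param dialect `"pdb-multimodel"` or `"frame-dump"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path,
                            dialect = c("pdb-multimodel", "frame-dump")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1) stop("write_structure: empty trajectory")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("write_structure: cannot open ",
                                           path, ": ", conditionMessage(e)))
  on.exit(close(con))
  at <- traj$top$atoms
  if (dialect == "pdb-multimodel") {
    multi <- n_frames(traj) > 1
    nm <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                 sprintf("%-4s", at$name))
    for (f in seq_len(n_frames(traj))) {
      if (multi) writeLines(sprintf("MODEL     %4d", f), con)
      co <- frame_coords(traj, f)
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        at$serial %% 100000, nm, substr(at$resname, 1, 3),
        substr(at$chain, 1, 1), at$resid %% 10000,
        co[, 1], co[, 2], co[, 3], at$occupancy, at$b,
        substr(at$element, 1, 2)), con)
      writeLines(if (multi) "ENDMDL" else "END", con)
    }
  } else {
    writeLines(c("TRAJDUMP v1", paste("NATOMS", traj$top$n_atoms)), con)
    writeLines(sprintf("ATOM %d %s %s %d %s %s", at$serial, at$name,
                       at$resname, at$resid, at$chain, at$molecule), con)
    for (f in seq_len(n_frames(traj))) {
      writeLines(sprintf("FRAME %.6g", traj$times[f]), con)
      co <- frame_coords(traj, f)
      writeLines(sprintf("%.6f %.6f %.6f", co[, 1], co[, 2], co[, 3]), con)
    }
  }
  invisible(path)
}

## ------------------------------------------------------------- parameters

#' Read a force-field parameter table
#'
#' Tab-separated text with header columns `residue_name`, `atom_name`,
#' `charge`, `lj_sigma`, `lj_epsilon`, `born_radius`, `vdw_radius`, `mass`.
#' `*` in `residue_name`/`atom_name` is a wildcard.
#'
#' @param path file path.
#' @return data.frame usable with [assign_parameters()].
#' @export
read_parameter_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "charge", "lj_sigma", "lj_epsilon",
            "born_radius", "vdw_radius", "mass")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("read_parameter_table: missing columns: ",
         paste(miss, collapse = ", "))
  tab
}

#' Attach force-field parameters to a topology
#'
#' Each atom is matched against the table by `(residue_name, atom_name)`,
#' with `*` wildcards; more specific rows win (exact pair, then exact
#' residue + wildcard atom, then wildcard residue + exact atom, then the
#' full wildcard row).
#'
#' @param top a [topology()].
#' @param table parameter table (see [read_parameter_table()]).
#' @param strict if TRUE, any unmatched atom is a hard error; otherwise
#'   unmatched atoms are reported via a warning and left `NA`.
#' @return topology with `charge`, `lj_sigma`, `lj_epsilon`, `born_radius`,
#'   `vdw_radius`, `mass` populated; unmatched serials in
#'   `attr(, "unmatched")`.
#' @export
assign_parameters <- function(top, table, strict = FALSE) {
  stopifnot(inherits(top, "topology"), is.data.frame(table))
  at <- top$atoms
  key_res <- trimws(table$residue_name)
  key_atm <- trimws(table$atom_name)
  specificity <- (key_res != "*") * 2 + (key_atm != "*")
  match_row <- function(res, atm) {
    hit <- which((key_res == res | key_res == "*") &
                 (key_atm == atm | key_atm == "*"))
    if (length(hit) == 0) return(NA_integer_)
    hit[which.max(specificity[hit])]
  }
  rows <- mapply(match_row, trimws(at$resname), trimws(at$name))
  unmatched <- which(is.na(rows))
  if (length(unmatched) > 0) {
    msg <- paste0("unmatched atoms: ",
                  paste(sprintf("%s/%s (serial %d)",
                                at$resname[unmatched], at$name[unmatched],
                                at$serial[unmatched]), collapse = ", "))
    if (strict) stop("assign_parameters: ", msg)
    warning("assign_parameters: ", msg)
  }
  ok <- !is.na(rows)
  for (col in c("charge", "lj_sigma", "lj_epsilon", "born_radius",
                "vdw_radius", "mass"))
    at[[col]][ok] <- table[[col]][rows[ok]]
  out <- topology(at)
  attr(out, "unmatched") <- at$serial[unmatched]
  out
}
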