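## Structure/trajectory I/O and geometry plumbing. PDB parsing is delegated
## to bio3d; GRO and XYZ are simple fixed-format text handled in-package.
## Coordinates are stored in nm internally (PDB and XYZ files are in Angstrom
## and converted on the way in/out).

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) "pdb"
  else if (ext == "gro") "gro"
  else if (ext == "xyz") "xyz"
  else stopf("cannot guess format from extension '%s'", ext)
}

topology_from_pdb_atom <- function(atom) {
  role <- ifelse(atom$elety %in% ATOM_ROLES, atom$elety, "other")
  chain <- ifelse(is.na(atom$chain) | atom$chain == "", "A", atom$chain)
  elem <- atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[^A-Za-z].*", "", atom$elety), 1L, 1L)
  makeTopology(data.frame(name = atom$elety, element = elem, chain = chain,
                          resid = atom$resno, resname = atom$resid,
                          role = role, stringsAsFactors = FALSE))
}

read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) == 0L) return(NULL)
  as.numeric(c(substr(ln[1L], 7, 15), substr(ln[1L], 16, 24),
               substr(ln[1L], 25, 33))) / 10
}

#' Read a molecular structure file
#'
#' Supported formats: PDB (via bio3d; Angstrom converted to nm), GRO (nm;
#' chains are not encoded in GRO, all atoms are assigned chain "A") and XYZ
#' (Angstrom; element symbols only, so a `topology` must be supplied).
#'
#' @param path file path.
#' @param format "pdb", "gro" or "xyz"; guessed from the extension by default.
#' @param topology required for XYZ input, optional otherwise (overrides the
#'   topology derived from the file).
#' @return a \linkS4class{Conformation}.
#' @export
readStructure <- function(path, format = format_from_path(path),
                          topology = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  if (format == "pdb") {
    p <- bio3d::read.pdb(path, verbose = FALSE)
    topo <- topology %||% topology_from_pdb_atom(p$atom)
    co <- matrix(p$xyz[1L, ], ncol = 3L, byrow = TRUE) / 10
  } else if (format == "gro") {
    parsed <- read_gro(path)
    topo <- topology %||% parsed$topology
    co <- parsed$coords
  } else {
    if (is.null(topology))
      stopf("XYZ files carry no atom metadata; supply a topology")
    topo <- topology
    fr <- read_xyz_frames(path, nAtoms(topology), max_frames = 1L)
    co <- fr$frames[[1L]]
  }
  if (nrow(co) != nAtoms(topo))
    stopf("file has %d atoms but topology has %d", nrow(co), nAtoms(topo))
  new("Conformation", topology = topo, coords = co)
}

#' Write a molecular structure file
#'
#' @param conf a \linkS4class{Conformation}.
#' @param path output path.
#' @param format "pdb", "gro" or "xyz"; guessed from the extension by default.
#' @param box optional orthorhombic box lengths (nm, length 3): written as a
#'   CRYST1 record (PDB) or the box line (GRO); ignored for XYZ.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(conf, path, format = format_from_path(path),
                           box = NULL) {
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  a <- atomData(conf)
  if (format == "pdb") {
    write_pdb_frames(path, a, list(conf@coords), box)
  } else if (format == "gro") {
    write_gro(path, a, conf@coords, box)
  } else {
    write_xyz_frames(path, a, list(conf@coords), times = 0)
  }
  invisible(path)
}

#' Read a multi-frame trajectory file
#'
#' Multi-model PDB (MODEL/ENDMDL blocks) and concatenated XYZ are supported.
#' Frame times are taken from the XYZ comment lines when present (written as
#' `t= <ps>` by \code{\link{writeTrajectory}}), otherwise synthesized as
#' k * dt.
#'
#' @param path file path.
#' @param format "pdb" or "xyz"; guessed from the extension by default.
#' @param topology required for XYZ, optional for PDB.
#' @param dt frame spacing in ps used when the file carries no times.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, format = format_from_path(path),
                           topology = NULL, dt = 100) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  format <- match.arg(format, c("pdb", "xyz"))
  times <- NULL
  if (format == "pdb") {
    check_pdb_models(path)
    p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    topo <- topology %||% topology_from_pdb_atom(p$atom)
    nf <- nrow(p$xyz)
    co <- array(NA_real_, dim = c(nAtoms(topo), 3L, nf))
    for (k in seq_len(nf))
      co[, , k] <- matrix(p$xyz[k, ], ncol = 3L, byrow = TRUE) / 10
    b <- read_cryst1(path)
    box <- if (is.null(b)) matrix(numeric(0), 0L, 3L) else
      matrix(rep(b, each = nf), nrow = nf)
  } else {
    if (is.null(topology))
      stopf("XYZ files carry no atom metadata; supply a topology")
    topo <- topology
    fr <- read_xyz_frames(path, nAtoms(topo))
    co <- array(unlist(fr$frames), dim = c(nAtoms(topo), 3L,
                                           length(fr$frames)))
    times <- fr$times
    box <- matrix(numeric(0), 0L, 3L)
  }
  nf <- dim(co)[3L]
  if (is.null(times) || anyNA(times)) times <- (seq_len(nf) - 1L) * dt
  new("Trajectory", topology = topo, coords = co, times = times, box = box)
}

#' Write a multi-frame trajectory file
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @param format "pdb" (MODEL/ENDMDL per frame, CRYST1 when a box is present)
#'   or "xyz" (concatenated, frame times in the comment lines).
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = format_from_path(path)) {
  format <- match.arg(format, c("pdb", "xyz"))
  a <- atomData(traj)
  frames <- lapply(seq_len(nFrames(traj)), function(k) traj@coords[, , k])
  if (format == "pdb") {
    box <- if (nrow(traj@box) > 0L) traj@box[1L, ] else NULL
    write_pdb_frames(path, a, frames, box)
  } else {
    write_xyz_frames(path, a, frames, times = traj@times)
  }
  invisible(path)
}

## ---- low-level writers/readers ------------------------------------------

write_pdb_frames <- function(path, atoms, frames, box = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
      box[1L] * 10, box[2L] * 10, box[3L] * 10), con)
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frames[[k]] * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(atoms)) %% 100000L,
      ifelse(nchar(atoms$name) < 4L, paste0(" ", atoms$name), atoms$name),
      atoms$resname, substr(atoms$chain, 1L, 1L), atoms$resid %% 10000L,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], atoms$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

## guard against silently mis-sized models before handing off to bio3d
check_pdb_models <- function(path) {
  ln <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", ln)
  if (length(model_starts) < 2L) return(invisible(TRUE))
  ends <- grep("^ENDMDL", ln)
  if (length(ends) < length(model_starts))
    stopf("trajectory frame %d is truncated (missing ENDMDL)",
          length(model_starts))
  counts <- vapply(seq_along(model_starts), function(i) {
    sum(grepl("^(ATOM|HETATM)", ln[model_starts[i]:ends[i]]))
  }, integer(1L))
  bad <- which(counts != counts[1L])
  if (length(bad) > 0L)
    stopf("frame %d has %d atoms, expected %d", bad[1L], counts[bad[1L]],
          counts[1L])
  invisible(TRUE)
}

write_gro <- function(path, atoms, xyz, box = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("written by betafold", con)
  writeLines(sprintf("%5d", nrow(atoms)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     atoms$resid %% 100000L, atoms$resname, atoms$name,
                     seq_len(nrow(atoms)) %% 100000L,
                     xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  b <- box %||% c(0, 0, 0)
  writeLines(sprintf("%10.5f%10.5f%10.5f", b[1L], b[2L], b[3L]), con)
}

read_gro <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 3L) stopf("GRO parse error at line 2: file too short")
  nat <- suppressWarnings(as.integer(trimws(ln[2L])))
  if (is.na(nat)) stopf("GRO parse error at line 2: bad atom count")
  if (length(ln) < 2L + nat)
    stopf("GRO parse error at line %d: expected %d atom lines",
          length(ln) + 1L, nat)
  rows <- ln[3:(2L + nat)]
  resid <- as.integer(substr(rows, 1, 5))
  resname <- trimws(substr(rows, 6, 10))
  name <- trimws(substr(rows, 11, 15))
  co <- cbind(as.numeric(substr(rows, 21, 28)),
              as.numeric(substr(rows, 29, 36)),
              as.numeric(substr(rows, 37, 44)))
  if (anyNA(co)) {
    bad <- which(apply(is.na(co), 1L, any))[1L]
    stopf("GRO parse error at line %d: bad coordinates", bad + 2L)
  }
  role <- ifelse(name %in% ATOM_ROLES, name, "other")
  topo <- makeTopology(data.frame(
    name = name, element = substr(gsub("[^A-Za-z].*", "", name), 1L, 1L),
    chain = "A", resid = resid, resname = resname, role = role,
    stringsAsFactors = FALSE))
  list(topology = topo, coords = co)
}

write_xyz_frames <- function(path, atoms, frames, times) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    writeLines(sprintf("%d", nrow(atoms)), con)
    writeLines(sprintf("t= %.6f ps", times[k]), con)
    xyz <- frames[[k]] * 10
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", atoms$element,
                       xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  }
}

read_xyz_frames <- function(path, natoms, max_frames = Inf) {
  ln <- readLines(path, warn = FALSE)
  frames <- list()
  times <- numeric(0)
  pos <- 1L
  k <- 0L
  while (pos <= length(ln) && nzchar(trimws(ln[pos])) && k < max_frames) {
    k <- k + 1L
    n <- suppressWarnings(as.integer(trimws(ln[pos])))
    if (is.na(n) || n != natoms)
      stopf("XYZ frame %d: atom count %s does not match topology (%d)",
            k, trimws(ln[pos]), natoms)
    if (pos + 1L + n > length(ln))
      stopf("XYZ frame %d is truncated", k)
    tm <- regmatches(ln[pos + 1L],
                     regexpr("t= *[-0-9.eE+]+", ln[pos + 1L]))
    times[k] <- if (length(tm) == 1L)
      as.numeric(sub("t= *", "", tm)) else NA_real_
    rows <- strsplit(trimws(ln[(pos + 2L):(pos + 1L + n)]), "[[:space:]]+")
    if (any(lengths(rows) < 4L)) stopf("XYZ frame %d is truncated", k)
    co <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L))) / 10
    if (anyNA(co)) stopf("XYZ frame %d: bad coordinates", k)
    frames[[k]] <- co
    pos <- pos + 2L + n
  }
  if (length(frames) == 0L) stopf("no frames found in %s", path)
  list(frames = frames, times = times)
}

## ---- selection and distances --------------------------------------------

#' Select atom indices by chain, residue, name or backbone role
#'
#' All predicates are optional and combined with AND; calling the function
#' with no predicates returns every atom exactly once.
#'
#' @param topology a \linkS4class{Topology} (or Conformation/Trajectory).
#' @param chain chain id(s).
#' @param resid residue index(es), 1-based within chain.
#' @param name atom name(s).
#' @param role backbone role(s) among N, H, CB, CA, C, O, other.
#' @return integer vector of atom indices.
#' @export
#' @examples
#' topo <- topology(presetConformation("extended", 4))
#' selectAtoms(topo, role = "CA", resid = 2:3)
selectAtoms <- function(topology, chain = NULL, resid = NULL, name = NULL,
                        role = NULL) {
  a <- if (is(topology, "Topology")) topology@atoms else atomData(topology)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(role)) keep <- keep & a$role %in% role
  which(keep)
}

#' Minimum-image distance between points
#'
#' Euclidean distance without a box; with an orthorhombic box each component
#' difference is shifted into [-L/2, L/2] first.
#'
#' @param a,b points: numeric length-3 vectors or n x 3 matrices.
#' @param box orthorhombic box lengths (nm, length 3) or NULL for open
#'   boundaries.
#' @return numeric distance(s) in nm.
#' @export
#' @examples
#' minimumImageDistance(c(0, 0, 0), c(0.9, 0, 0), box = c(1, 1, 1))
minimumImageDistance <- function(a, b, box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d <- a - b
  if (!is.null(box)) {
    for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
  }
  out <- sqrt(rowSums(d * d))
  if (length(out) == 1L) out[[1L]] else out
}

#' Read a table of NOE distance restraints
#'
#' The expected CSV columns are `chain_i`, `resid_i`, `atom_names_i` (one or
#' more atom names separated by `|`, a chemical-equivalence group),
#' `chain_j`, `resid_j`, `atom_names_j` and `r_exp_nm` (the experimental
#' upper distance bound in nm).
#'
#' @param path CSV file path.
#' @return data.frame of restraints, one row each.
#' @export
readNOETable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain_i", "resid_i", "atom_names_i", "chain_j", "resid_j",
            "atom_names_j", "r_exp_nm")
  if (!all(need %in% names(d)))
    stopf("NOE table must have columns: %s", paste(need, collapse = ", "))
  if (any(d$r_exp_nm <= 0)) stopf("r_exp_nm must be positive")
  d
}
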