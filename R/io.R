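#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d). For multi-model files the
#' requested model is used (first by default). Records with missing or
#' non-numeric coordinates raise a parse error naming the offending line
#' rather than propagating NA coordinates.
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported here.
#' @param model model number to extract from multi-model files.
#' @return a [Structure].
#' @export
read_structure <- function(path, format = "pdb", model = 1L) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed ATOM record (truncated coordinates) at line ", i,
           " of ", path)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM record (unparseable coordinates) at line ", i,
           " of ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nat <- nrow(pdb$atom)
  xyz <- pdb$xyz
  if (model > nrow(xyz)) stop("model ", model, " not present (file has ",
                              nrow(xyz), ")")
  elem <- pdb$atom$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nat)
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", pdb$atom$elety)), 1, 1))
  elem <- ifelse(is.na(elem) | !nzchar(trimws(elem)), guess, trimws(elem))
  ch <- pdb$atom$chain
  ch[is.na(ch)] <- "A"
  atoms <- data.frame(eleno = pdb$atom$eleno, name = pdb$atom$elety,
                      element = toupper(elem), resid = pdb$atom$resno,
                      resname = pdb$atom$resid, chain = ch,
                      stringsAsFactors = FALSE)
  Structure(atoms, unflatten_coords(xyz[model, ]))
}

#' Write a structure to a PDB file
#'
#' @param structure a [Structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path, xyz = flatten_coords(structure$coords),
                   type = rep("ATOM", nrow(a)), resno = a$resid,
                   resid = a$resname, eleno = a$eleno, elety = a$name,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

guess_traj_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, dcd = "dcd", xyz = "xyz", pdb = "pdb",
         stop("cannot infer trajectory format from extension '", ext, "'"))
}

#' Read a coordinate trajectory
#'
#' Supported formats: binary DCD (`"dcd"`), multi-model PDB (`"pdb"`), and
#' plain XYZ (`"xyz"`; coordinates assumed Angstrom). Frames are returned in
#' file order; an atom count differing from the topology is an error.
#'
#' @param path trajectory file.
#' @param topology the [Structure] the frames refer to.
#' @param format `"dcd"`, `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @return a [Trajectory].
#' @export
read_trajectory <- function(path, topology, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_traj_format(path)
  format <- match.arg(format, c("dcd", "pdb", "xyz"))
  nat <- n_atoms(topology)
  xyz <- switch(format,
    dcd = bio3d::read.dcd(path, verbose = FALSE),
    pdb = bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)$xyz,
    xyz = read_xyz_frames(path))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nat)
    stop("trajectory has ", ncol(xyz) / 3, " atoms per frame but topology has ",
         nat)
  Trajectory(topology, xyz)
}

#' Write a trajectory
#'
#' Formats: `"dcd"` (CHARMM-style binary), `"pdb"` (multi-model PDB) or
#' `"xyz"` (plain text). DCD stores single-precision coordinates.
#'
#' @param trajectory a [Trajectory].
#' @param path output file.
#' @param format `"dcd"`, `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = "auto") {
  if (format == "auto") format <- guess_traj_format(path)
  format <- match.arg(format, c("dcd", "pdb", "xyz"))
  switch(format,
    dcd = write_dcd(trajectory$xyz, path),
    pdb = {
      a <- trajectory$topology$atoms
      bio3d::write.pdb(file = path, xyz = trajectory$xyz,
                       type = rep("ATOM", nrow(a)), resno = a$resid,
                       resid = a$resname, eleno = a$eleno, elety = a$name,
                       chain = a$chain, elesy = a$element)
    },
    xyz = write_xyz_frames(trajectory, path))
  invisible(path)
}

# Plain xyz: per frame "natoms\ncomment\n<name x y z> ..."
read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("xyz parse error at line ", i, ": expected atom count")
    if (i + 1L + nat > length(lines)) stop("truncated xyz file: frame at line ",
                                           i, " promises ", nat, " atoms")
    block <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(block), "[[:space:]]+")
    co <- t(vapply(fields, function(f) {
      v <- suppressWarnings(as.numeric(f[2:4]))
      if (any(is.na(v))) stop("xyz parse error: bad coordinate line '",
                              paste(f, collapse = " "), "'")
      v
    }, numeric(3)))
    frames[[length(frames) + 1L]] <- flatten_coords(co)
    i <- i + 2L + nat
  }
  do.call(rbind, frames)
}

write_xyz_frames <- function(trajectory, path) {
  nat <- n_atoms(trajectory$topology)
  el <- trajectory$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    co <- frame_coords(trajectory, f)
    writeLines(c(as.character(nat), paste("frame", f)), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el, co[, 1], co[, 2],
                       co[, 3]), con)
  }
}

# Minimal CHARMM DCD writer (no unit cell); fortran records are
# length-prefixed/suffixed int32 blocks, coordinates single precision.
write_dcd <- function(xyz, path) {
  nf <- as.integer(nrow(xyz))
  nat <- as.integer(ncol(xyz) / 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  put_rec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf            # frames in file
  icntrl[2] <- 1L            # first step
  icntrl[3] <- 1L            # save interval
  icntrl[4] <- nf
  icntrl[20] <- 24L          # charmm version stamp
  put_rec(function(rc) {
    writeBin(charToRaw("CORD"), rc)
    writeBin(icntrl, rc, size = 4L, endian = "little")
  })
  title <- formatC("written by nqogate", width = -80)
  put_rec(function(rc) {
    writeBin(1L, rc, size = 4L, endian = "little")
    writeBin(charToRaw(title), rc)
  })
  put_rec(function(rc) writeBin(nat, rc, size = 4L, endian = "little"))
  idx <- seq_len(nat)
  for (f in seq_len(nf)) {
    co <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    for (d in 1:3)
      put_rec(function(rc) writeBin(as.numeric(co[, d]), rc, size = 4L,
                                    endian = "little"))
  }
  invisible(path)
}
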