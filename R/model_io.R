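# Topology/Frame model and structure/trajectory I/O.
#
# Atom ordinals are 1-based row indices into topology$atoms; residue_ids are
# kept verbatim from the source file so residue numbers from the literature
# (e.g. Glu908, Glu918) can be used directly in selections.

#' Residue names recognised as water
#'
#' Covers the common water dialects found in crystal structures and MD
#' topologies (HOH, TIP3/TIP3P/TIP4, SOL, WAT, SPC). All are normalised to a
#' single internal water flag.
#'
#' @return Character vector of residue names.
#' @export
water_residue_names <- function() {
  c("HOH", "TIP3", "TIP3P", "TIP4", "SOL", "WAT", "SPC")
}

#' Build a topology from an atom table
#'
#' Assembles the package's internal topology: a validated atom table with
#' donor/acceptor/hydrogen roles and hydrogen-to-parent covalent records
#' inferred from the reference coordinates (nearest heavy atom in the same
#' residue, within 1.9 Angstrom).
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_id`, `chain_id` and optionally `element` (derived from the atom
#'   name when absent).
#' @param xyz n x 3 numeric matrix of reference coordinates (Angstrom), used
#'   only to infer hydrogen-parent connectivity.
#' @param water_names residue names to flag as water.
#' @return An object of class `topology`: list with `atoms` (data.frame
#'   gaining `ordinal`, `element`, `is_water`, `role`), `h_parent` (integer
#'   vector, parent heavy-atom ordinal for hydrogens, `NA` otherwise) and
#'   `water_names`.
#' @export
topology <- function(atoms, xyz, water_names = water_residue_names()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  needed <- c("atom_name", "residue_name", "residue_id", "chain_id")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  xyz <- as_xyz_matrix(xyz, nrow(atoms))
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms$chain_id <- as.character(atoms$chain_id)
  if (is.null(atoms$element) || all(is.na(atoms$element))) {
    atoms$element <- guess_element(atoms$atom_name)
  } else {
    atoms$element <- toupper(as.character(atoms$element))
    idx <- is.na(atoms$element) | atoms$element == ""
    atoms$element[idx] <- guess_element(atoms$atom_name[idx])
  }
  atoms$ordinal <- seq_len(nrow(atoms))
  atoms$is_water <- atoms$residue_name %in% water_names

  key <- paste(atoms$chain_id, atoms$residue_id, atoms$atom_name, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("ambiguous atom record: duplicate (chain, residue_id, atom_name) = ",
         dup)
  }

  h_parent <- rep(NA_integer_, nrow(atoms))
  is_h <- atoms$element == "H"
  if (any(is_h)) {
    res_key <- paste(atoms$chain_id, atoms$residue_id, sep = "|")
    for (i in which(is_h)) {
      mates <- which(res_key == res_key[i] & !is_h)
      if (length(mates) == 0) {
        stop("hydrogen atom ", atoms$atom_name[i], " in residue ",
             atoms$residue_name[i], atoms$residue_id[i],
             " has no heavy atom in its residue to bond to")
      }
      d <- sqrt(colSums((t(xyz[mates, , drop = FALSE]) - xyz[i, ])^2))
      j <- mates[which.min(d)]
      if (min(d) > 1.9) {
        stop("hydrogen atom ", atoms$atom_name[i], " in residue ",
             atoms$residue_name[i], atoms$residue_id[i],
             " is ", round(min(d), 2), " A from the nearest heavy atom; ",
             "cannot assign a covalent parent")
      }
      h_parent[i] <- j
    }
  }

  has_h <- tabulate(h_parent[!is.na(h_parent)], nbins = nrow(atoms)) > 0
  role <- rep("other", nrow(atoms))
  polar <- atoms$element %in% c("O", "N")
  role[polar & has_h] <- "donor_heavy"
  role[polar & !has_h] <- "acceptor_heavy"
  role[is_h] <- "hydrogen"
  atoms$role <- role

  # each water residue must carry exactly one oxygen
  if (any(atoms$is_water)) {
    w <- atoms[atoms$is_water, ]
    n_o <- tapply(w$element == "O", paste(w$chain_id, w$residue_id), sum)
    if (any(n_o != 1)) {
      stop("water residue without exactly one oxygen: ",
           names(n_o)[which(n_o != 1)[1]])
    }
  }

  structure(
    list(atoms = atoms, h_parent = h_parent, water_names = water_names),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  nw <- length(unique(paste(x$atoms$chain_id, x$atoms$residue_id)[x$atoms$is_water]))
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_id))) - nw,
      "non-water residues,", nw, "waters\n")
  invisible(x)
}

#' Construct a single trajectory frame
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param time frame time in picoseconds (non-negative).
#' @param box optional length-3 orthorhombic box edges (Angstrom); when
#'   present all distance computations use the minimum-image convention.
#' @return Object of class `frame`.
#' @export
frame <- function(xyz, time = 0, box = NULL) {
  xyz <- as_xyz_matrix(xyz)
  stopifnot(length(time) == 1, is.finite(time), time >= 0)
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    box <- as.numeric(box)
  }
  structure(list(xyz = xyz, time = as.numeric(time), box = box),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat("frame: t =", x$time, "ps,", nrow(x$xyz), "atoms",
      if (!is.null(x$box)) paste0("(box ", paste(round(x$box, 2), collapse = " x "), " A)"),
      "\n")
  invisible(x)
}

as_xyz_matrix <- function(xyz, n_expected = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3) stop("coordinates must be an n x 3 matrix")
  if (!is.null(n_expected) && nrow(xyz) != n_expected) {
    stop("coordinate count (", nrow(xyz), ") does not match atom count (",
         n_expected, ")")
  }
  dimnames(xyz) <- NULL
  xyz
}

guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$|^[0-9]+", "", atom_name))
  nm <- sub("^([0-9]*)", "", nm)
  el <- substr(nm, 1, 1)
  # two-letter elements that occur in practice
  el[nm %in% c("CL", "CLA")] <- "CL"
  el[nm %in% c("NA", "SOD")] <- "NA"
  el[grepl("^MG", nm)] <- "MG"
  el
}

#' Load a structure file into a topology and its frames
#'
#' Reads a (possibly multi-MODEL) PDB file through `bio3d::read.pdb()` and
#' converts it to the package topology/frame model. All ATOM and HETATM
#' records are kept; waters are recognised by residue name
#' (see [water_residue_names()]); crystallographic waters without hydrogens
#' are permitted and remain usable under the heavy-atom-only hydrogen-bond
#' criterion.
#'
#' @param path PDB file path.
#' @param water_names residue names flagged as water.
#' @param dt_ps time spacing assigned to successive MODELs (ps).
#' @return list with `topology` and `frames` (list of [frame()] objects, one
#'   per MODEL, sharing the atom order of the topology).
#' @export
load_structure <- function(path, water_names = water_residue_names(),
                           dt_ps = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- data.frame(
    atom_name = pdb$atom$elety,
    residue_name = pdb$atom$resid,
    residue_id = pdb$atom$resno,
    chain_id = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
    element = pdb$atom$elesy,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  box <- read_cryst1_box(path)
  frames <- lapply(seq_len(n_frames), function(i) {
    frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE),
          time = (i - 1) * dt_ps, box = box)
  })
  top <- topology(atoms, frames[[1]]$xyz, water_names = water_names)
  list(topology = top, frames = frames)
}

# CRYST1 a b c: ignore the degenerate 1x1x1 placeholder box
read_cryst1_box <- function(path) {
  hdr <- readLines(path, n = 50L, warn = FALSE)
  cl <- grep("^CRYST1", hdr, value = TRUE)
  if (length(cl) == 0) return(NULL)
  abc <- suppressWarnings(as.numeric(c(
    substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33)
  )))
  if (anyNA(abc) || all(abc <= 1)) return(NULL)
  abc
}

#' Load a coordinate trajectory against an existing topology
#'
#' Supports DCD (via `bio3d::read.dcd()`) and multi-MODEL PDB files. DCD
#' stores no time axis, so frame times are `dt_ps * (index - 1)`; the
#' trajectory can be subsampled by requesting a `stride_ps` that is an
#' integer multiple of `dt_ps`.
#'
#' @param topology a [topology()] the frames must match in atom count.
#' @param path trajectory file (`.dcd` or `.pdb`).
#' @param dt_ps time spacing between stored frames (ps).
#' @param stride_ps desired sampling interval (ps); default keeps every frame.
#' @param box optional length-3 box to attach to every frame (DCD cell
#'   records are not interpreted).
#' @return list of [frame()] objects with strictly increasing times.
#' @export
load_trajectory <- function(topology, path, dt_ps = 1, stride_ps = dt_ps,
                            box = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.xtc$", path, ignore.case = TRUE)) {
    stop("XTC trajectories are not supported; convert to DCD or ",
         "multi-MODEL PDB")
  }
  if (stride_ps < dt_ps) stop("stride_ps must be >= dt_ps")
  k <- stride_ps / dt_ps
  if (abs(k - round(k)) > 1e-9) {
    stop("stride_ps must be an integer multiple of dt_ps")
  }
  k <- as.integer(round(k))

  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  } else {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("unparseable trajectory file ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (is.null(box)) box <- read_cryst1_box(path)
  }
  if (nrow(xyz) == 0) stop("empty trajectory: ", path)
  n_atoms <- ncol(xyz) / 3
  if (n_atoms != nrow(topology$atoms)) {
    stop("trajectory atom count (", n_atoms,
         ") does not match topology atom count (", nrow(topology$atoms), ")")
  }
  keep <- seq(1, nrow(xyz), by = k)
  lapply(keep, function(i) {
    frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE),
          time = (i - 1) * dt_ps, box = box)
  })
}

#' Write a structure (or multi-frame fixture) as PDB
#'
#' @param topology a [topology()].
#' @param frames a single [frame()] or list of frames; multiple frames are
#'   written as MODEL/ENDMDL blocks sharing the topology's atom order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, frames, path) {
  stopifnot(inherits(topology, "topology"))
  if (inherits(frames, "frame")) frames <- list(frames)
  at <- topology$atoms
  fmt_atom <- function(i, xyz) {
    nm <- at$atom_name[i]
    # PDB column convention: 1-3 letter names start in column 14
    nm_fmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    sprintf("%-6s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (at$is_water[i]) "HETATM" else "ATOM", i %% 100000, nm_fmt,
            substr(at$residue_name[i], 1, 4), substr(at$chain_id[i], 1, 1),
            at$residue_id[i] %% 10000,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, at$element[i])
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  box <- frames[[1]]$box
  if (!is.null(box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1], box[2], box[3], 90, 90, 90), con)
  }
  multi <- length(frames) > 1
  for (f in seq_along(frames)) {
    xyz <- as_xyz_matrix(frames[[f]]$xyz, nrow(at))
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(vapply(seq_len(nrow(at)), fmt_atom, character(1), xyz = xyz), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write tabular results as TSV
#'
#' Plain-text tab-delimited output with a header row and the column order of
#' the input, suitable for downstream plotting.
#'
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    write.table(records, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

#' Select atom ordinals from a topology
#'
#' All supplied filters are combined with AND; `NULL` filters are ignored.
#'
#' @param topology a [topology()].
#' @param residue_id integer residue id(s), as numbered in the source file.
#' @param atom_name atom name(s), PDB convention.
#' @param chain_id chain id(s).
#' @param residue_name residue name(s).
#' @param element element symbol(s).
#' @param must_resolve error (rather than return `integer(0)`) when nothing
#'   matches.
#' @return Integer vector of atom ordinals (1-based).
#' @export
atom_select <- function(topology, residue_id = NULL, atom_name = NULL,
                        chain_id = NULL, residue_name = NULL, element = NULL,
                        must_resolve = FALSE) {
  stopifnot(inherits(topology, "topology"))
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(residue_id)) keep <- keep & at$residue_id %in% residue_id
  if (!is.null(atom_name)) keep <- keep & at$atom_name %in% atom_name
  if (!is.null(chain_id)) keep <- keep & at$chain_id %in% chain_id
  if (!is.null(residue_name)) keep <- keep & at$residue_name %in% residue_name
  if (!is.null(element)) keep <- keep & at$element %in% element
  out <- which(keep)
  if (must_resolve && length(out) == 0) {
    stop("selection resolved to zero atoms (residue_id=",
         paste(residue_id, collapse = ","), " atom_name=",
         paste(atom_name, collapse = ","), ")")
  }
  out
}

#' Ordinals of all water oxygens
#'
#' @param topology a [topology()].
#' @return Integer vector of ordinals, one per water residue.
#' @export
water_oxygens <- function(topology) {
  at <- topology$atoms
  which(at$is_water & at$element == "O")
}

#' Hydrogens covalently bonded to a heavy atom
#'
#' @param topology a [topology()].
#' @param ordinal heavy-atom ordinal.
#' @return Integer vector of hydrogen ordinals (possibly empty).
#' @export
bonded_hydrogens <- function(topology, ordinal) {
  which(!is.na(topology$h_parent) & topology$h_parent == ordinal)
}
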