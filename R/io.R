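# On-disk representation: tab-delimited snapshot tables, multi-model PDB /
# concatenated XYZ coordinates, JSON manifests and results. TSV is the
# canonical dialect ('.' decimal, UTF-8, 1e-6 precision); frame alignment
# between the energy table and the coordinate file is positional.

#' Write a trajectory's snapshot table (TSV)
#'
#' Columns: `frame`, `state`, `energy_eV`, then `q_neutral_<label>` and
#' `q_cation_<label>` for the 8 analysis-region base labels of the system.
#'
#' @param traj A `ddna_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_table <- function(traj, path) {
  stopifnot(inherits(traj, "ddna_trajectory"))
  labs <- traj$qm1_labels
  tab <- data.frame(frame = traj$frame_id, state = traj$state,
                    energy_eV = sprintf("%.6f", traj$energy),
                    stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    tab[[paste0("q_neutral_", labs[i])]] <- sprintf("%.6f", traj$q_neutral[, i])
  }
  for (i in seq_along(labs)) {
    tab[[paste0("q_cation_", labs[i])]] <- sprintf("%.6f", traj$q_cation[, i])
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a snapshot table (TSV) against a duplex system
#'
#' Validates the schema (all 16 charge columns for the system's analysis
#' region, known state labels, unique frame ids, parseable numerics) and
#' returns the records in file order.
#'
#' @param path Path to a TSV written by [write_snapshot_table()] or by an
#'   external converter following the same schema.
#' @param system The [dna_duplex()] the table belongs to (defines the
#'   expected charge-column labels).
#' @return A `ddna_trajectory` (without coordinates). An empty table with a
#'   valid header yields a zero-frame trajectory with a warning.
#' @export
read_snapshot_table <- function(path, system) {
  stopifnot(inherits(system, "dna_duplex"))
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  labs <- system$qm1$label
  need <- c("frame", "state", "energy_eV",
            paste0("q_neutral_", labs), paste0("q_cation_", labs))
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stopf("snapshot table %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    warnf("snapshot table %s has a header but no rows", path)
    return(new_trajectory(system$name, character(0), integer(0), numeric(0),
                          matrix(numeric(0), 0, 8, dimnames = list(NULL, labs)),
                          matrix(numeric(0), 0, 8, dimnames = list(NULL, labs)),
                          qm1_labels = labs))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !tab[[col]] %in% c("NA", ""))
    if (length(bad)) {
      stopf("malformed numeric '%s' in column %s, line %d of %s",
            tab[[col]][bad[1]], col, bad[1] + 1L, path)
    }
    v
  }
  frame <- num("frame")
  if (anyDuplicated(frame)) {
    stopf("duplicate frame_id %s in %s", frame[anyDuplicated(frame)], path)
  }
  state <- tab$state
  bad_state <- which(!state %in% c("neutral", "cation"))
  if (length(bad_state)) {
    stopf("unknown state label '%s' at line %d of %s",
          state[bad_state[1]], bad_state[1] + 1L, path)
  }
  q_neu <- sapply(paste0("q_neutral_", labs), num)
  q_cat <- sapply(paste0("q_cation_", labs), num)
  if (nrow(tab) == 1L) { q_neu <- matrix(q_neu, 1L); q_cat <- matrix(q_cat, 1L) }
  colnames(q_neu) <- colnames(q_cat) <- labs
  st <- unique(state)
  new_trajectory(system$name, if (length(st) == 1L) st else state,
                 as.integer(frame), num("energy_eV"), q_neu, q_cat,
                 qm1_labels = labs)
}

#' Write trajectory coordinates as a multi-model PDB
#'
#' Standard fixed-column ATOM records (three pseudo-atoms per base named
#' P1/P2/P3, residues `DA`/`DC`/`DG`/`DT`, chains A and B), one
#' MODEL/ENDMDL block per frame. PDB coordinates carry 3 decimals.
#'
#' @param traj A `ddna_trajectory` with coordinates, or a bare
#'   `n_frames x n_atoms x 3` array.
#' @param path Output path.
#' @param system Optional [dna_duplex()] for residue names; generic `DN`
#'   residues are written otherwise.
#' @return `path`, invisibly.
#' @export
write_coordinates_pdb <- function(traj, path, system = NULL) {
  coords <- frame_array(traj)
  n <- dim(coords)[1]; na <- dim(coords)[2]
  res <- rep("DN ", na)
  chain <- rep("A", na)
  resno <- rep(seq_len(ceiling(na / 3)), each = 3L)[seq_len(na)]
  if (!is.null(system) && na == N_PSEUDO_ATOMS) {
    bases <- c(strsplit(system$strand53, "")[[1]], strsplit(system$strand35, "")[[1]])
    res <- paste0("D", rep(bases, each = 3L))
    chain <- rep(c("A", "B"), each = 36L)
    resno <- rep(rep(1:12, each = 3L), 2L)
  }
  atom <- rep(c("P1", "P2", "P3"), length.out = na)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n)) {
    writeLines(sprintf("MODEL %8d", f), con)
    lines <- sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     seq_len(na), atom, res, chain, resno,
                     coords[f, , 1], coords[f, , 2], coords[f, , 3], 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write trajectory coordinates as concatenated XYZ
#'
#' One XYZ block per frame (atom count, comment, then `El x y z` lines with
#' 6 decimals).
#'
#' @inheritParams write_coordinates_pdb
#' @return `path`, invisibly.
#' @export
write_coordinates_xyz <- function(traj, path) {
  coords <- frame_array(traj)
  n <- dim(coords)[1]; na <- dim(coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("C %14.6f %14.6f %14.6f",
                       coords[f, , 1], coords[f, , 2], coords[f, , 3]), con)
  }
  invisible(path)
}

#' Read per-frame coordinate sets (multi-model PDB or XYZ)
#'
#' The format is inferred from the extension unless given. Atom counts must
#' be constant across frames. Frames align positionally with the snapshot
#' table; [assemble_trajectory()] enforces the count consistency check.
#'
#' @param path Path to a `.pdb` (MODEL/ENDMDL blocks) or `.xyz`
#'   (concatenated blocks) file.
#' @param format `"auto"` (default), `"pdb"` or `"xyz"`.
#' @return An `n_frames x n_atoms x 3` array.
#' @export
read_coordinates <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "xyz")) ext else
      stopf("cannot infer coordinate format from '%s'", path)
  }
  lines <- readLines(path)
  frames <- if (format == "pdb") parse_pdb_frames(lines, path) else
    parse_xyz_frames(lines, path)
  counts <- vapply(frames, nrow, integer(1))
  if (length(unique(counts)) > 1L) {
    stopf("varying atom counts across frames of %s: %s", path,
          paste(unique(counts), collapse = ", "))
  }
  arr <- array(NA_real_, dim = c(length(frames), counts[1], 3L))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  arr
}

parse_pdb_frames <- function(lines, path) {
  frames <- list(); cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (startsWith(ln, "MODEL")) {
      cur <- character(0)
    } else if (startsWith(ln, "ENDMDL")) {
      if (is.null(cur)) stopf("ENDMDL without MODEL in %s", path)
      frames[[length(frames) + 1L]] <- cur
      cur <- NULL
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      if (is.null(cur)) cur <- character(0)  # single-model file without MODEL
      cur <- c(cur, ln)
    }
  }
  if (!is.null(cur) && length(cur)) frames[[length(frames) + 1L]] <- cur
  if (!length(frames)) stopf("no coordinate frames found in %s", path)
  lapply(frames, function(rows) {
    x <- as.numeric(substr(rows, 31, 38))
    y <- as.numeric(substr(rows, 39, 46))
    z <- as.numeric(substr(rows, 47, 54))
    if (any(is.na(x) | is.na(y) | is.na(z))) {
      stopf("malformed ATOM coordinates in %s", path)
    }
    cbind(x, y, z)
  })
}

parse_xyz_frames <- function(lines, path) {
  frames <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na <= 0L) stopf("bad atom count at line %d of %s", i, path)
    if (i + 1L + na > length(lines)) stopf("truncated XYZ block at line %d of %s", i, path)
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    mat <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(mat))) stopf("malformed XYZ coordinates near line %d of %s", i, path)
    frames[[length(frames) + 1L]] <- mat
    i <- i + 2L + na
  }
  if (!length(frames)) stopf("no coordinate frames found in %s", path)
  frames
}

#' Attach a coordinate file to a snapshot table positionally
#'
#' @param traj A `ddna_trajectory` from [read_snapshot_table()].
#' @param coords Array from [read_coordinates()] (or a path).
#' @return The trajectory with coordinates attached; errors if the frame
#'   counts disagree.
#' @export
assemble_trajectory <- function(traj, coords) {
  stopifnot(inherits(traj, "ddna_trajectory"))
  if (is.character(coords)) coords <- read_coordinates(coords)
  if (dim(coords)[1] != n_frames(traj)) {
    stopf("frame count mismatch: table has %d frames, coordinates have %d",
          n_frames(traj), dim(coords)[1])
  }
  traj$coords <- coords
  traj
}

#' Write a run manifest (JSON)
#'
#' Records the system, trajectory lengths, units declaration, seed and the
#' full generator configuration for provenance. The energy unit is always
#' eV.
#'
#' @param system A [dna_duplex()].
#' @param config A [generator_config()].
#' @param path Output path.
#' @param n_neutral,n_cation Trajectory lengths.
#' @param note Optional provenance note.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(system, config, path, n_neutral = config$n_frames,
                           n_cation = config$n_frames,
                           note = "synthetic ensemble") {
  man <- list(system = system$name,
              strand53 = system$strand53, strand35 = system$strand35,
              n_neutral = n_neutral, n_cation = n_cation,
              units = list(energy = "eV", charge = "e", length = "model units"),
              seed = config$seed, config = unclass(config), provenance = note)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an analysis results document (JSON)
#'
#' Serializes a (possibly nested) results list; classed summary objects are
#' flattened to plain lists. NaN/Inf values are serialized as `null` with a
#' warning. Round-trips losslessly through [read_results()] at full double
#' precision.
#'
#' @param report A named list (sections may be `marcus_redox`,
#'   `deloc_summary`, `convergence_report` objects or plain values).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path) {
  plain <- results_to_plain(report)
  if (scrub_nonfinite(plain)) {
    warnf("non-finite value(s) in results serialized as null")
  }
  plain <- rapply(plain, function(x) {
    if (is.numeric(x)) x[!is.finite(x)] <- NA
    x
  }, how = "replace")
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "columns")
  invisible(path)
}

results_to_plain <- function(x) {
  if (inherits(x, c("marcus_redox", "deloc_summary", "convergence_report",
                    "cluster_model", "generator_config", "reference_electrode"))) {
    x <- unclass(x)
  }
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, results_to_plain))
  x
}

scrub_nonfinite <- function(x) {
  if (is.list(x)) {
    return(any(vapply(x, scrub_nonfinite, logical(1))))
  }
  is.numeric(x) && any(!is.finite(x))
}

#' Read back a results document
#'
#' @param path Path to a JSON file from [write_results()].
#' @return The parsed list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
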