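#' Write a configuration in GRO format
#'
#' Fixed-format GRO dialect: title line, atom count, one line per atom
#' (residue number/name, atom name, atom number, position in nm, optional
#' velocity in nm/ps), and the box line.
#'
#' @param config An `md_config`.
#' @param file Output path.
#' @param title Title line content.
#' @return `file`, invisibly.
#' @export
write_gro <- function(config, file, title = "ipswater configuration") {
  n <- n_atoms(config)
  lines <- character(n + 3)
  lines[1] <- title
  lines[2] <- sprintf("%5d", n)
  has_vel <- !is.null(config$velocities)
  for (i in seq_len(n)) {
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    config$mol_id[i] %% 100000, "SOL",
                    substr(config$atom_name[i], 1, 5), i %% 100000,
                    config$positions[i, 1], config$positions[i, 2],
                    config$positions[i, 3])
    if (has_vel)
      base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                   config$velocities[i, 1],
                                   config$velocities[i, 2],
                                   config$velocities[i, 3]))
    lines[i + 2] <- base
  }
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f", config$box[1], config$box[2],
                          config$box[3])
  writeLines(lines, file)
  invisible(file)
}

#' Read a GRO file
#'
#' Parses the fixed-format GRO dialect. For all-water files (atom names
#' beginning with O/H in triplets), per-atom masses, charges and LJ
#' coefficients are filled in from the SPC/E model; otherwise they are
#' zero and must be set by the caller.
#'
#' @param file Path to a `.gro` file.
#' @param model Water model used to assign parameters.
#' @return An `md_config`.
#' @export
read_gro <- function(file, model = water_model()) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(n + 2)]
  resid <- as.integer(substr(at, 1, 5))
  name <- trimws(substr(at, 11, 15))
  pos <- cbind(as.numeric(substr(at, 21, 28)),
               as.numeric(substr(at, 29, 36)),
               as.numeric(substr(at, 37, 44)))
  vel <- NULL
  if (nchar(at[1]) >= 68) {
    vel <- cbind(as.numeric(substr(at, 45, 52)),
                 as.numeric(substr(at, 53, 60)),
                 as.numeric(substr(at, 61, 68)))
  }
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
  mol_id <- cumsum(c(1L, diff(resid) != 0))
  is_o <- startsWith(name, "O")
  mass <- ifelse(is_o, model$mass_O, model$mass_H)
  charge <- ifelse(is_o, model$q_O, model$q_H)
  md_config(box = box, positions = pos, velocities = vel, mol_id = mol_id,
            atom_name = name, mass = mass, charge = charge,
            c6 = ifelse(is_o, model$c6, 0), c12 = ifelse(is_o, model$c12, 0))
}

#' Write a trajectory in XYZ-with-box format
#'
#' Plain XYZ frames whose comment line carries the time stamp (ps) and box
#' edges (nm); coordinates are written in nm.
#'
#' @param traj An `md_trajectory` (see [run_simulation()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(traj, file) {
  n <- dim(traj$frames)[1]
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(dim(traj$frames)[3])) {
    writeLines(sprintf("%d", n), con)
    writeLines(sprintf("t= %.6f ps box= %.6f %.6f %.6f nm",
                       traj$frame_time[f], traj$box[1], traj$box[2], traj$box[3]), con)
    xyz <- traj$frames[, , f]
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", traj$atom_name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(file)
}
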