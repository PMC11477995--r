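# Species records: construction, validation, JSON and XYZ I/O, and
# rotational data derived from geometry.

# Standard atomic weights (amu), enough for the chemistry handled here.
.atomic_masses <- c(
  H = 1.008, He = 4.002602, Li = 6.94, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998403163, Na = 22.98976928,
  Mg = 24.305, P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.0983, Ca = 40.078, Br = 79.904, I = 126.90447
)

#' Atom table constructor
#'
#' Builds the ordered atom table of a species: element symbol, atomic mass
#' (amu) and Cartesian coordinates (Angstrom). Masses default to the
#' standard atomic-weight table.
#'
#' @param element character vector of element symbols.
#' @param x,y,z Cartesian coordinates, Angstrom.
#' @param mass atomic masses, amu; `NA` entries are filled from the
#'   element table.
#' @return data.frame with columns element, mass, x, y, z.
#' @export
atom_table <- function(element, x, y, z, mass = NA_real_) {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  mass <- rep_len(as.numeric(mass), n)
  unknown <- setdiff(element, names(.atomic_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fill <- is.na(mass)
  mass[fill] <- unname(.atomic_masses[element[fill]])
  if (any(mass <= 0)) stop("atomic masses must be positive", call. = FALSE)
  data.frame(element = element, mass = mass,
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             stringsAsFactors = FALSE)
}

#' Create a species record
#'
#' A species record holds one chemical species' quantum-chemistry results
#' and metadata: geometry, harmonic frequencies, electronic energy, net
#' charge, spin multiplicity, explicit-water bookkeeping and (optionally)
#' precomputed free energies or per-protocol solvation free energies.
#' Energies are stored internally in J mol^-1; `energy_unit` records the
#' unit tag the inputs were expressed in (preserved on serialization).
#'
#' @param label free-text identifier.
#' @param substituent para-substituent label (e.g. `"H"`, `"OCH3"`,
#'   `"SO3-"`) or free text.
#' @param role `"protonated"` (HA) or `"deprotonated"` (A-).
#' @param charge net charge, elementary charges.
#' @param multiplicity spin multiplicity (>= 1).
#' @param is_radical logical; defaults to `multiplicity > 1`.
#' @param atoms atom table from [atom_table()], or `NULL`.
#' @param frequencies harmonic wavenumbers, cm^-1. Negative entries flag
#'   imaginary modes and are rejected by the validator unless dropped.
#' @param electronic_energy electronic energy in `energy_unit` (`NA` if
#'   absent).
#' @param free_energy_gas,free_energy_sol optional precomputed gas-phase /
#'   solution-phase Gibbs free energies in `energy_unit`.
#' @param solvation_energies optional named numeric vector or list mapping
#'   protocol labels (`"P1"`..`"P6"`) to solvation free energies in
#'   `energy_unit`.
#' @param explicit_waters number of explicit water molecules in the model.
#' @param water_motif free-text water-placement label (e.g. `"HO"`, `"NH"`,
#'   `"2HO"`, `"HOA90"`).
#' @param symmetry_number external rotational symmetry number (>= 1).
#' @param linearity `"auto"` (classify from geometry), `"linear"` or
#'   `"nonlinear"`.
#' @param energy_unit unit tag the energy arguments are expressed in.
#' @param validate run [validate_species_record()] before returning.
#' @return object of class `species_record` (energies in J mol^-1).
#' @export
species_record <- function(label, substituent = "", role = "protonated",
                           charge = 0L, multiplicity = 1L,
                           is_radical = multiplicity > 1,
                           atoms = NULL, frequencies = numeric(),
                           electronic_energy = NA_real_,
                           free_energy_gas = NA_real_,
                           free_energy_sol = NA_real_,
                           solvation_energies = NULL,
                           explicit_waters = 0L, water_motif = "",
                           symmetry_number = 1L, linearity = "auto",
                           energy_unit = "j/mol", validate = TRUE) {
  solv <- NULL
  if (!is.null(solvation_energies) && length(solvation_energies) > 0) {
    solv <- vapply(solvation_energies, function(v) energy_to_jmol(v, energy_unit),
                   numeric(1))
    names(solv) <- names(solvation_energies)
  }
  rec <- structure(list(
    label = as.character(label),
    substituent = as.character(substituent),
    role = match.arg(role, c("protonated", "deprotonated")),
    charge = as.integer(charge),
    multiplicity = as.integer(multiplicity),
    is_radical = isTRUE(is_radical),
    atoms = atoms,
    frequencies = as.numeric(frequencies),
    electronic_energy = energy_to_jmol(as.numeric(electronic_energy), energy_unit),
    free_energy_gas = energy_to_jmol(as.numeric(free_energy_gas), energy_unit),
    free_energy_sol = energy_to_jmol(as.numeric(free_energy_sol), energy_unit),
    solvation_energies = solv,
    explicit_waters = as.integer(explicit_waters),
    water_motif = as.character(water_motif),
    symmetry_number = as.integer(symmetry_number),
    linearity = match.arg(linearity, c("auto", "linear", "nonlinear")),
    energy_unit = tolower(energy_unit)
  ), class = "species_record")
  if (validate) rec <- validate_species_record(rec) else rec
}

#' Validate a species record
#'
#' Checks structural invariants: multiplicity >= 1; recognized elements and
#' positive masses; the real-frequency count against the 3N-6 / 3N-5 / 0
#' rule (a deviation is reported as a warning, since rotors and constrained
#' models legitimately deviate); consistency of the radical flag with the
#' multiplicity (warning only). Imaginary modes (negative wavenumbers) are
#' an error by default; `allow_imaginary = "drop"` removes them with a
#' warning, matching the convention that all species are optimized minima.
#'
#' @param record a `species_record`.
#' @param allow_imaginary `"error"` or `"drop"`.
#' @return the (possibly modified) record, invisibly classed as before.
#' @export
validate_species_record <- function(record,
                                    allow_imaginary = c("error", "drop")) {
  allow_imaginary <- match.arg(allow_imaginary)
  if (!inherits(record, "species_record")) {
    stop("not a species_record", call. = FALSE)
  }
  if (is.na(record$multiplicity) || record$multiplicity < 1) {
    stop("multiplicity must be >= 1", call. = FALSE)
  }
  if (record$symmetry_number < 1) {
    stop("symmetry_number must be >= 1", call. = FALSE)
  }
  if (record$explicit_waters < 0) {
    stop("explicit_waters must be >= 0", call. = FALSE)
  }
  if (record$is_radical != (record$multiplicity > 1)) {
    warning("is_radical flag disagrees with multiplicity for '",
            record$label, "'", call. = FALSE)
  }
  if (!is.null(record$atoms) && nrow(record$atoms) > 0) {
    unknown <- setdiff(record$atoms$element, names(.atomic_masses))
    if (length(unknown) > 0) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(record$atoms$mass <= 0)) {
      stop("atomic masses must be positive", call. = FALSE)
    }
  }
  freqs <- record$frequencies
  if (any(freqs < 0)) {
    if (allow_imaginary == "drop") {
      warning("dropping ", sum(freqs < 0), " imaginary mode(s) from '",
              record$label, "'", call. = FALSE)
      record$frequencies <- freqs[freqs >= 0]
    } else {
      stop("imaginary mode (negative frequency) in '", record$label,
           "'; species must be an optimized minimum", call. = FALSE)
    }
  }
  if (!is.null(record$atoms) && nrow(record$atoms) > 0 &&
      length(record$frequencies) > 0) {
    n <- nrow(record$atoms)
    expected <- if (n == 1) 0L else c(3L * n - 6L, 3L * n - 5L)
    if (!(length(record$frequencies) %in% expected)) {
      warning("'", record$label, "': ", length(record$frequencies),
              " real frequencies for ", n, " atoms (expected ",
              paste(expected, collapse = " or "), ")", call. = FALSE)
    }
  }
  record
}

#' @export
print.species_record <- function(x, ...) {
  cat(sprintf("<species_record> %s (%s, %s)\n", x$label,
              x$substituent, x$role))
  cat(sprintf("  charge %+d, multiplicity %d%s, %d atom(s), %d mode(s)\n",
              x$charge, x$multiplicity,
              if (x$is_radical) " (radical)" else "",
              if (is.null(x$atoms)) 0L else nrow(x$atoms),
              length(x$frequencies)))
  if (!is.na(x$electronic_energy)) {
    cat(sprintf("  E_elec %.6f Hartree\n",
                jmol_to_unit(x$electronic_energy, "hartree")))
  }
  if (x$explicit_waters > 0) {
    cat(sprintf("  explicit waters: %d (%s)\n", x$explicit_waters,
                x$water_motif))
  }
  if (!is.null(x$solvation_energies)) {
    cat("  solvation protocols:", paste(names(x$solvation_energies),
                                        collapse = ", "), "\n")
  }
  invisible(x)
}

.energy_field <- function(value_jmol, unit) {
  if (is.na(value_jmol)) return(NULL)
  list(value = jmol_to_unit(value_jmol, unit), unit = unit)
}

#' Write a species record to JSON
#'
#' Serializes the record to the documented JSON schema (shipped at
#' `system.file("extdata", "species-record-schema.json", package = "qcpka")`).
#' Energies are written back in the record's original unit tag, so a
#' read/write round trip reproduces the file's unit convention.
#'
#' @param record a validated `species_record`.
#' @param path output file path.
#' @export
write_species_record <- function(record, path) {
  u <- record$energy_unit
  obj <- list(
    label = record$label,
    substituent = record$substituent,
    role = record$role,
    charge = record$charge,
    multiplicity = record$multiplicity,
    is_radical = record$is_radical,
    atoms = if (is.null(record$atoms)) list() else record$atoms,
    frequencies = record$frequencies,
    electronic_energy = .energy_field(record$electronic_energy, u),
    free_energy_gas = .energy_field(record$free_energy_gas, u),
    free_energy_sol = .energy_field(record$free_energy_sol, u),
    solvation_energies = if (is.null(record$solvation_energies)) NULL else
      lapply(as.list(record$solvation_energies),
             function(v) list(value = jmol_to_unit(v, u), unit = u)),
    explicit_waters = record$explicit_waters,
    water_motif = record$water_motif,
    symmetry_number = record$symmetry_number,
    linearity = record$linearity
  )
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.read_energy_field <- function(field, what) {
  if (is.null(field)) return(list(value = NA_real_, unit = NULL))
  if (is.null(field$value) || is.null(field$unit)) {
    stop("field '", what, "' must carry both 'value' and 'unit'",
         call. = FALSE)
  }
  list(value = energy_to_jmol(field$value, field$unit),
       unit = tolower(field$unit))
}

#' Read a species record from JSON
#'
#' Parses and validates a species-record JSON file; all energies are
#' normalized to J mol^-1 on return (the file's unit tag is retained in
#' `$energy_unit` for round-tripping).
#'
#' @param path path to a species-record JSON file.
#' @param allow_imaginary imaginary-mode policy, see
#'   [validate_species_record()].
#' @return a validated `species_record`.
#' @export
read_species_record <- function(path, allow_imaginary = c("error", "drop")) {
  allow_imaginary <- match.arg(allow_imaginary)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  for (f in c("label", "charge", "multiplicity")) {
    if (is.null(obj[[f]])) {
      stop("species record '", path, "' missing required field '", f, "'",
           call. = FALSE)
    }
  }
  atoms <- NULL
  if (!is.null(obj$atoms) && length(obj$atoms) > 0 &&
      (is.data.frame(obj$atoms) || length(obj$atoms) > 0)) {
    a <- obj$atoms
    if (is.data.frame(a) && nrow(a) > 0) {
      atoms <- atom_table(a$element, a$x, a$y, a$z,
                          mass = if ("mass" %in% names(a)) a$mass else NA_real_)
    }
  }
  ee <- .read_energy_field(obj$electronic_energy, "electronic_energy")
  gg <- .read_energy_field(obj$free_energy_gas, "free_energy_gas")
  gs <- .read_energy_field(obj$free_energy_sol, "free_energy_sol")
  unit <- ee$unit %||% gg$unit %||% gs$unit %||% "j/mol"
  solv <- NULL
  if (!is.null(obj$solvation_energies) && length(obj$solvation_energies) > 0) {
    solv <- vapply(obj$solvation_energies, function(fld) {
      .read_energy_field(fld, "solvation_energies")$value
    }, numeric(1))
  }
  rec <- structure(list(
    label = obj$label,
    substituent = obj$substituent %||% "",
    role = obj$role %||% "protonated",
    charge = as.integer(obj$charge),
    multiplicity = as.integer(obj$multiplicity),
    is_radical = isTRUE(obj$is_radical %||% (obj$multiplicity > 1)),
    atoms = atoms,
    frequencies = as.numeric(obj$frequencies %||% numeric()),
    electronic_energy = ee$value,
    free_energy_gas = gg$value,
    free_energy_sol = gs$value,
    solvation_energies = solv,
    explicit_waters = as.integer(obj$explicit_waters %||% 0L),
    water_motif = obj$water_motif %||% "",
    symmetry_number = as.integer(obj$symmetry_number %||% 1L),
    linearity = obj$linearity %||% "auto",
    energy_unit = unit
  ), class = "species_record")
  validate_species_record(rec, allow_imaginary = allow_imaginary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a standard XYZ geometry file
#'
#' First line: atom count; second line: comment; then one `element x y z`
#' line per atom (coordinates in Angstrom). Masses are filled from the
#' standard atomic-weight table.
#'
#' @param path path to an XYZ file.
#' @return atom table (see [atom_table()]).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("XYZ header is not a positive atom count: '", lines[1], "'",
         call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("XYZ file declares ", n, " atoms but lists ", length(body),
         call. = FALSE)
  }
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bad <- vapply(toks, length, integer(1)) < 4
  if (any(bad)) {
    stop("malformed XYZ atom line: '", body[which(bad)[1]], "'",
         call. = FALSE)
  }
  element <- vapply(toks, `[[`, character(1), 1)
  coord <- function(i) vapply(toks, function(t) as.numeric(t[[i]]), numeric(1))
  atom_table(element, coord(2), coord(3), coord(4))
}

#' Write a standard XYZ geometry file
#'
#' @param atoms atom table.
#' @param path output file path.
#' @param comment second-line comment.
#' @export
write_xyz <- function(atoms, path, comment = "") {
  lines <- c(nrow(atoms), comment,
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     atoms$element, atoms$x, atoms$y, atoms$z))
  writeLines(lines, path)
  invisible(path)
}

#' Principal moments of inertia
#'
#' Builds the inertia tensor about the center of mass and diagonalizes it.
#' Moments are returned in kg m^2, ascending. Linearity is classified by
#' comparing the smallest moment to `linear_tol` times the largest (a
#' single atom is monatomic with all moments zero).
#'
#' @param atoms atom table (masses amu, coordinates Angstrom).
#' @param symmetry_number external symmetry number carried into the result.
#' @param linear_tol relative tolerance for the linearity classification.
#' @return object of class `rotational_data` with fields
#'   `principal_moments` (kg m^2, `I_A <= I_B <= I_C`), `linearity`
#'   (`"monatomic"`, `"linear"` or `"nonlinear"`) and `symmetry_number`.
#' @export
principal_moments <- function(atoms, symmetry_number = 1L,
                              linear_tol = 1e-6) {
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("principal_moments requires at least one atom", call. = FALSE)
  }
  m <- atoms$mass
  if (any(m <= 0)) stop("atomic masses must be positive", call. = FALSE)
  if (nrow(atoms) == 1) {
    return(structure(list(principal_moments = c(0, 0, 0),
                          linearity = "monatomic",
                          symmetry_number = as.integer(symmetry_number)),
                     class = "rotational_data"))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  tensor <- matrix(c(
    sum(m * (y^2 + z^2)), -sum(m * x * y),       -sum(m * x * z),
    -sum(m * x * y),       sum(m * (x^2 + z^2)), -sum(m * y * z),
    -sum(m * x * z),      -sum(m * y * z),        sum(m * (x^2 + y^2))
  ), nrow = 3, byrow = TRUE)
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0 & abs(ev) < 1e-12 * max(abs(ev), 1)] <- 0  # clip eigen noise
  moments <- ev * .const$amu * .const$angstrom^2
  linearity <- if (moments[1] < linear_tol * moments[3]) "linear" else "nonlinear"
  structure(list(principal_moments = moments,
                 linearity = linearity,
                 symmetry_number = as.integer(symmetry_number)),
            class = "rotational_data")
}

#' @export
print.rotational_data <- function(x, ...) {
  cat(sprintf("<rotational_data> %s, sigma = %d\n", x$linearity,
              x$symmetry_number))
  cat(sprintf("  I = %.4e, %.4e, %.4e kg m^2\n",
              x$principal_moments[1], x$principal_moments[2],
              x$principal_moments[3]))
  invisible(x)
}
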