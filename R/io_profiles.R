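## Readers/writers for the sectioned (Turbomole-like) COSMO output file,
## radii parameter tables and XYZ geometries; sigma-profile histograms; and
## the run_cosmo() orchestration that strings the whole pipeline together.

## ---- XYZ and radii ---------------------------------------------------------

#' Read a standard XYZ file
#'
#' Count line, comment line (may be blank), then `element x y z` rows in
#' Angstrom.
#'
#' @param source File path or character vector of lines.
#' @return Data frame with columns `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source) else source
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error: first line must be the atom count")
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) < n)
    stop(sprintf("XYZ parse error: count line says %d atoms but only %d rows found",
                 n, length(rows)))
  rows <- rows[seq_len(n)]
  parts <- strsplit(trimws(rows), "\\s+")
  if (any(lengths(parts) < 4)) stop("XYZ parse error: malformed atom row")
  data.frame(element = vapply(parts, `[[`, "", 1),
             x = as.numeric(vapply(parts, `[[`, "", 2)),
             y = as.numeric(vapply(parts, `[[`, "", 3)),
             z = as.numeric(vapply(parts, `[[`, "", 4)))
}

#' Read an atomic radii parameter file
#'
#' Plain text, one `element radius` pair per line (radius in Angstrom;
#' `#` comments and blank lines ignored). The multiplicative `scale`
#' (default 1.18, the +18% convention for tabulated van der Waals radii)
#' is stored and applied at lookup time.
#'
#' @param source File path or character vector of lines.
#' @param scale Uniform scale factor applied to tabulated radii.
#' @return A `radii_table`: list with named numeric `radii` (tabulated,
#'   unscaled) and `scale`.
#' @export
read_radii_file <- function(source, scale = 1.18) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source) else source
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  el <- vapply(parts, `[[`, "", 1)
  r <- as.numeric(vapply(parts, `[[`, "", 2))
  if (anyDuplicated(el))
    stop("radii file has duplicate entries for: ",
         paste(unique(el[duplicated(el)]), collapse = ", "))
  if (any(!is.finite(r) | r <= 0))
    stop("radii file has nonpositive or malformed radii")
  structure(list(radii = stats::setNames(r, el), scale = scale),
            class = "radii_table")
}

#' Look up applied (scaled) radii for elements
#'
#' @param table A [read_radii_file()] result.
#' @param elements Character vector of element symbols.
#' @return Scaled radii in Angstrom (`tabulated * scale`).
#' @export
radii_lookup <- function(table, elements) {
  missing <- setdiff(elements, names(table$radii))
  if (length(missing))
    stop("no radius tabulated for element(s): ",
         paste(missing, collapse = ", "))
  unname(table$radii[elements]) * table$scale
}

## ---- solute model serialization -------------------------------------------

#' Read / write a classical solute model
#'
#' Plain-text format, one particle per line:
#' `nucleus x y z Z` or `cloud x y z q alpha` (Angstrom, e, Bohr^-2; `#`
#' comments ignored).
#'
#' @param source File path or character vector of lines.
#' @return A [solute_model()].
#' @export
read_solute_model <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source) else source
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  kind <- vapply(parts, `[[`, "", 1)
  num <- function(p, i) as.numeric(p[[i]])
  nuc <- parts[kind == "nucleus"]
  cl <- parts[kind == "cloud"]
  if (any(!kind %in% c("nucleus", "cloud")))
    stop("solute model parse error: lines must start with 'nucleus' or 'cloud'")
  nuclei <- data.frame(x = vapply(nuc, num, 0, 2), y = vapply(nuc, num, 0, 3),
                       z = vapply(nuc, num, 0, 4), Z = vapply(nuc, num, 0, 5))
  clouds <- data.frame(x = vapply(cl, num, 0, 2), y = vapply(cl, num, 0, 3),
                       z = vapply(cl, num, 0, 4), q = vapply(cl, num, 0, 5),
                       alpha = vapply(cl, num, 0, 6))
  solute_model(nuclei, clouds)
}

#' @rdname read_solute_model
#' @param solute A [solute_model()].
#' @param destination File path.
#' @export
write_solute_model <- function(solute, destination) {
  ln <- c(
    sprintf("nucleus %.10g %.10g %.10g %.10g", solute$nuclei$x,
            solute$nuclei$y, solute$nuclei$z, solute$nuclei$Z),
    sprintf("cloud %.10g %.10g %.10g %.10g %.10g", solute$clouds$x,
            solute$clouds$y, solute$clouds$z, solute$clouds$q,
            solute$clouds$alpha))
  writeLines(ln, destination)
  invisible(destination)
}

## ---- COSMO output file -----------------------------------------------------

#' Write a COSMO output file
#'
#' Sectioned, line-oriented text similar to the Turbomole COSMO file:
#' a `$cosmo` settings block, `$cosmo_energy`, a `$coord_car`-style
#' geometry block (`element x y z radius`, Angstrom) and a
#' `$segment_information` block with one row per segment
#' (`index atom x y z area charge sigma potential`). Numeric fields round
#' trip through [read_cosmo_file()] at printed precision.
#'
#' @param record A `cosmo_record` as produced by [run_cosmo()] (or
#'   assembled by hand with the same fields: `settings`, `energies`,
#'   `geometry`, `segments`).
#' @param destination File path.
#' @return `destination`, invisibly.
#' @export
write_cosmo_file <- function(record, destination) {
  if (is.null(record$segments) || nrow(record$segments) == 0)
    stop("refusing to write a COSMO file with an empty segment block")
  st <- record$settings
  fmt <- function(k, v) sprintf("  %s = %s", k, v)
  lines <- c(
    "$cosmo",
    fmt("method", st$method), fmt("cavity", st$cavity),
    fmt("ndiv", st$ndiv),
    fmt("rsolv", sprintf("%.6f", st$rsolv)),
    fmt("mfactor", sprintf("%.6f", st$mfactor)),
    fmt("screen", st$screen),
    fmt("epsilon", format(st$eps)),
    fmt("charge_correction", st$charge_correction),
    fmt("potcorr", format(st$potcorr)),
    if (!is.null(st$f_N)) fmt("f_N", sprintf("%.12f", st$f_N)),
    if (!is.null(st$f_e)) fmt("f_e", sprintf("%.12f", st$f_e)),
    fmt("nseg", format(nrow(record$segments))),
    "$cosmo_energy",
    fmt("E_gas", sprintf("%.12e", record$energies$E_gas)),
    fmt("E_solvated", sprintf("%.12e", record$energies$E_solvated)),
    fmt("E_dielectric", sprintf("%.12e", record$energies$E_dielectric)),
    "$coord_car",
    sprintf("  %-4s %16.10f %16.10f %16.10f %12.6f",
            record$geometry$element, record$geometry$x, record$geometry$y,
            record$geometry$z, record$geometry$radius),
    "$segment_information",
    "# index atom x y z area charge sigma potential",
    sprintf("  %5d %5d %18.10e %18.10e %18.10e %18.10e %18.10e %18.10e %18.10e",
            record$segments$index, record$segments$atom,
            record$segments$x, record$segments$y, record$segments$z,
            record$segments$area, record$segments$charge,
            record$segments$sigma, record$segments$potential),
    "$end")
  writeLines(lines, destination)
  invisible(destination)
}

#' Read a COSMO output file
#'
#' Inverse of [write_cosmo_file()]; tolerant of extra whitespace and `#`
#' comment lines.
#'
#' @param source File path or character vector of lines.
#' @return A `cosmo_record` list with `settings`, `energies`, `geometry`,
#'   `segments`.
#' @export
read_cosmo_file <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source) else source
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  sec_at <- grep("^\\$", lines)
  if (!length(sec_at)) stop("COSMO file parse error: no $ section headers")
  secs <- list()
  for (i in seq_along(sec_at)) {
    name <- sub("^\\$", "", trimws(lines[sec_at[i]]))
    name <- strsplit(name, "\\s+")[[1]][1]
    to <- if (i < length(sec_at)) sec_at[i + 1] - 1 else length(lines)
    secs[[name]] <- if (to > sec_at[i]) lines[(sec_at[i] + 1):to] else character(0)
  }
  for (need in c("cosmo", "cosmo_energy", "coord_car", "segment_information"))
    if (is.null(secs[[need]]))
      stop("COSMO file parse error: missing $", need, " block")
  kv <- function(block) {
    parts <- strsplit(trimws(block), "\\s*=\\s*")
    stats::setNames(lapply(parts, function(p) p[2]),
                    vapply(parts, `[[`, "", 1))
  }
  st <- kv(secs$cosmo)
  en <- kv(secs$cosmo_energy)
  settings <- list(method = st$method, cavity = st$cavity, ndiv = st$ndiv,
                   rsolv = as.numeric(st$rsolv),
                   mfactor = as.numeric(st$mfactor), screen = st$screen,
                   eps = as.numeric(st$epsilon),
                   charge_correction = st$charge_correction,
                   potcorr = as.logical(st$potcorr))
  if (!is.null(st$f_N)) settings$f_N <- as.numeric(st$f_N)
  if (!is.null(st$f_e)) settings$f_e <- as.numeric(st$f_e)
  nseg <- as.integer(st$nseg)
  energies <- list(E_gas = as.numeric(en$E_gas),
                   E_solvated = as.numeric(en$E_solvated),
                   E_dielectric = as.numeric(en$E_dielectric))
  gp <- strsplit(trimws(secs$coord_car), "\\s+")
  geometry <- data.frame(element = vapply(gp, `[[`, "", 1),
                         x = as.numeric(vapply(gp, `[[`, "", 2)),
                         y = as.numeric(vapply(gp, `[[`, "", 3)),
                         z = as.numeric(vapply(gp, `[[`, "", 4)),
                         radius = as.numeric(vapply(gp, `[[`, "", 5)))
  sp <- strsplit(trimws(secs$segment_information), "\\s+")
  if (!is.na(nseg) && length(sp) != nseg)
    stop(sprintf(
      "COSMO file parse error: header declares %d segments but %d rows found",
      nseg, length(sp)))
  col <- function(i) as.numeric(vapply(sp, `[[`, "", i))
  segments <- data.frame(index = as.integer(col(1)), atom = as.integer(col(2)),
                         x = col(3), y = col(4), z = col(5), area = col(6),
                         charge = col(7), sigma = col(8), potential = col(9))
  structure(list(settings = settings, energies = energies,
                 geometry = geometry, segments = segments),
            class = "cosmo_record")
}

## ---- sigma profile ---------------------------------------------------------

#' Surface charge density histogram (sigma-profile)
#'
#' Each segment contributes its area `s_i` to the bin containing its
#' charge density `sigma_i = q_i / s_i` (e/Angstrom^2). Out-of-range
#' densities are clamped into the end bins with a warning, so the total
#' weight always equals the total cavity area. The hydrogen-bond donor /
#' acceptor cutoffs conventionally drawn on these profiles are carried
#' along as metadata.
#'
#' @param segments A `cosmo_segments` object (areas in Angstrom^2).
#' @param charges Charge per segment (e), same length.
#' @param bin_width Bin width in e/Angstrom^2 (default 0.001).
#' @param range Histogram range (default `c(-0.025, 0.025)`).
#' @param hb_cutoff Hydrogen-bond cutoff magnitude (default 0.0084
#'   e/Angstrom^2): donor region `sigma < -hb_cutoff`, acceptor
#'   `sigma > +hb_cutoff`.
#' @return A `sigma_profile`: data-frame-like list with `breaks`,
#'   `centers`, `weights` (area per bin), `hb_donor_cutoff`,
#'   `hb_acceptor_cutoff`.
#' @export
sigma_profile <- function(segments, charges, bin_width = 0.001,
                          range = c(-0.025, 0.025), hb_cutoff = 0.0084) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(charges) != n_segments(segments))
    stop("one charge per segment required")
  sigma <- charges / segments$areas
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2])
    breaks <- c(breaks, range[2])
  nb <- length(breaks) - 1
  if (any(sigma < range[1] | sigma > range[2]))
    warning("sigma values outside the histogram range were clamped to the end bins")
  idx <- findInterval(sigma, breaks, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nb] <- nb
  weights <- vapply(seq_len(nb), function(b) sum(segments$areas[idx == b]),
                    numeric(1))
  structure(list(breaks = breaks,
                 centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 weights = weights,
                 hb_donor_cutoff = -hb_cutoff, hb_acceptor_cutoff = hb_cutoff),
            class = "sigma_profile")
}

#' Write a sigma-profile as CSV
#' @param profile A [sigma_profile()].
#' @param destination File path.
#' @export
write_sigma_profile <- function(profile, destination) {
  utils::write.csv(data.frame(sigma = profile$centers,
                              area = profile$weights),
                   destination, row.names = FALSE)
  invisible(destination)
}

## ---- orchestration ---------------------------------------------------------

## minimal element table for default classical charge models in XYZ runs
.element_Z <- c(H = 1, He = 2, Li = 3, B = 5, C = 6, N = 7, O = 8, F = 9,
                Na = 11, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Br = 35,
                I = 53)

#' Pipeline configuration
#'
#' Out-of-the-box defaults mirror the engine's reference configuration:
#' YK method, vdW cavity, `fine` tessellation, `rsolv = 1.3` Angstrom,
#' `mfactor = 1.0`, ideal (conductor) screening, Lagrangian outlying
#' charge correction, automatic linear-solver choice and radii scale 1.18.
#'
#' @param fixture Optional fixture name (see [make_fixture()]).
#' @param seed Integer seed (fixture generation / any sampling).
#' @param xyz,radii,solute Optional file paths for geometry, radii table
#'   and a serialized solute model (used when `fixture` is `NULL`). When
#'   `solute` is missing, a neutral classical model is built from the
#'   elements (`Z` nuclei plus neutralizing Gaussian clouds with exponent
#'   `cloud_alpha`).
#' @param method `"yk"` or `"ks"`.
#' @param cavity `"vdw"` or `"ses"`.
#' @param ndiv `"coarse"`, `"fine"`, `"xfine"`.
#' @param rsolv Probe radius, Angstrom.
#' @param mfactor Merge-distance scale.
#' @param screen `"ideal"`, `"ks"`, `"st"`.
#' @param eps Relative permittivity (for `"ks"`/`"st"` screening).
#' @param charge_correction `"lagrangian"`, `"scale"` or `"off"`.
#' @param lineq `"auto"`, `"dense"` or `"iterative"`.
#' @param potcorr Legacy energy path: correct charges but keep the
#'   uncorrected potential in the energy expression.
#' @param radii_scale Uniform scale on tabulated radii (default 1.18).
#' @param cloud_alpha Gaussian exponent for default XYZ charge models
#'   (Bohr^-2).
#' @param ofac,rmin GEPOL auxiliary-sphere parameters.
#' @return A `cosmo_config` list.
#' @export
cosmo_config <- function(fixture = NULL, seed = 1L, xyz = NULL, radii = NULL,
                         solute = NULL, method = c("yk", "ks"),
                         cavity = c("vdw", "ses"),
                         ndiv = c("fine", "coarse", "xfine"), rsolv = 1.3,
                         mfactor = 1.0, screen = c("ideal", "ks", "st"),
                         eps = Inf,
                         charge_correction = c("lagrangian", "scale", "off"),
                         lineq = c("auto", "dense", "iterative"),
                         potcorr = FALSE, radii_scale = 1.18,
                         cloud_alpha = 1.2, ofac = 0.8, rmin = 0.5) {
  structure(list(fixture = fixture, seed = as.integer(seed), xyz = xyz,
                 radii = radii, solute = solute, method = match.arg(method),
                 cavity = match.arg(cavity), ndiv = match.arg(ndiv),
                 rsolv = rsolv, mfactor = mfactor,
                 screen = match.arg(screen), eps = eps,
                 charge_correction = match.arg(charge_correction),
                 lineq = match.arg(lineq), potcorr = potcorr,
                 radii_scale = radii_scale, cloud_alpha = cloud_alpha,
                 ofac = ofac, rmin = rmin),
            class = "cosmo_config")
}

default_solute_for_geometry <- function(geometry, cloud_alpha) {
  Z <- .element_Z[geometry$element]
  if (any(is.na(Z)))
    stop("no nuclear charge tabulated for element(s): ",
         paste(unique(geometry$element[is.na(Z)]), collapse = ", "))
  pos <- as.matrix(geometry[, c("x", "y", "z")])
  solute_model(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          Z = unname(Z)),
               data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          q = -unname(Z), alpha = cloud_alpha))
}

#' Run the full COSMO pipeline
#'
#' Radii, spheres, cavity (vdW or SES) with segment merging, split
#' nuclear/electronic potentials, Coulomb matrix (KS or YK), conductor
#' solve, outlying charge correction, corrected potential, dielectric
#' scaling, energies, COSMO-file record and sigma-profile. Stage-level
#' quantities (segment counts, defects before/after correction, scaling
#' factors, energies) are collected in the `log` element.
#'
#' @param config A [cosmo_config()].
#' @return List of class `cosmo_result` with elements `energy`
#'   (`E_diel`/`E_diel_kcal`/`E_diel_legacy`, correction mode, flags),
#'   `record` (COSMO file record), `profile` ([sigma_profile()]),
#'   `cavity`, `charges` (final corrected, scaled charges and split
#'   parts), `potentials`, and `log`.
#' @export
run_cosmo <- function(config = cosmo_config()) {
  ## ---- inputs
  if (!is.null(config$fixture)) {
    fx <- make_fixture(config$fixture, config$seed)
    solute <- fx$solute
    spheres <- fx$spheres
    geometry <- data.frame(element = paste0("X", seq_len(nrow(spheres))),
                           x = spheres$x, y = spheres$y, z = spheres$z,
                           radius = spheres$radius)
  } else {
    if (is.null(config$xyz) || is.null(config$radii))
      stop("either a fixture name or xyz + radii files are required")
    geometry <- read_xyz(config$xyz)
    rt <- read_radii_file(config$radii, scale = config$radii_scale)
    geometry$radius <- radii_lookup(rt, geometry$element)
    spheres <- make_spheres(as.matrix(geometry[, c("x", "y", "z")]),
                            geometry$radius)
    solute <- if (!is.null(config$solute)) read_solute_model(config$solute)
      else default_solute_for_geometry(geometry, config$cloud_alpha)
  }
  ## ---- cavity
  params <- cavity_params(config$cavity, config$ndiv, config$rsolv,
                          config$mfactor, config$ofac, config$rmin)
  cavity <- if (config$cavity == "ses") build_ses_cavity(spheres, params)
    else {
      cav <- build_vdw_cavity(spheres, params$level)
      d_min <- compute_d_min(params$level, params$rsolv, params$mfactor)
      cav$segments <- merge_segments(cav$segments, d_min)
      cav
    }
  segs <- cavity$segments
  m <- n_segments(segs)
  ## ---- potentials and conductor solve
  pot <- solute_potential(solute, segs$centers)
  A <- if (config$method == "ks") build_A_ks(segs)
    else build_A_yk(segs, yk_exponents(segs, params$level))
  sc <- solve_screening(A, phi_N = pot$phi_N, phi_e = pot$phi_e,
                        method = config$lineq)
  Q_N <- solute$Q_N; Q_e <- solute$Q_e
  defect_before <- charge_defect(sc$q, Q_N + Q_e)
  ## ---- outlying charge correction
  f_N <- NULL; f_e <- NULL; lambda <- NULL
  if (config$charge_correction == "scale") {
    cs <- correct_scale(sc$q_N, sc$q_e, Q_N, Q_e)
    q_prime <- cs$q; q_Np <- cs$q_N; q_ep <- cs$q_e
    f_N <- cs$f_N; f_e <- cs$f_e
  } else if (config$charge_correction == "lagrangian") {
    cl <- correct_lagrangian(A, pot$phi, Q_N + Q_e, method = config$lineq)
    q_prime <- cl$q; lambda <- cl$lambda
    ## outlying charge is electronic: book the whole adjustment there
    q_Np <- sc$q_N; q_ep <- sc$q_e + (q_prime - sc$q)
  } else {
    q_prime <- sc$q; q_Np <- sc$q_N; q_ep <- sc$q_e
  }
  defect_after <- charge_defect(q_prime, Q_N + Q_e)
  ## ---- corrected potential (unless legacy potcorr or correction off)
  if (config$charge_correction == "off") {
    phi_used <- pot$phi; phi_e_used <- pot$phi_e; pot_corrected <- FALSE
  } else if (config$potcorr) {
    phi_used <- pot$phi; phi_e_used <- pot$phi_e; pot_corrected <- FALSE
  } else {
    cp <- corrected_potential(A, q_prime, pot$phi_N)
    phi_used <- cp$phi; phi_e_used <- cp$phi_e; pot_corrected <- TRUE
  }
  ## ---- dielectric scaling (applied to the final corrected charges; the
  ##      potential stays the conductor-consistent one, so E_diel is linear
  ##      in f_eps)
  f_eps <- scale_factor(config$screen, config$eps)
  q_final <- q_prime * f_eps
  q_N_final <- q_Np * f_eps
  q_e_final <- q_ep * f_eps
  E <- dielectric_energy(phi_used, q_final)
  E_legacy <- dielectric_energy(pot$phi, q_final)
  energy <- structure(list(
    E_diel = E$hartree, E_diel_kcal = E$kcal,
    E_diel_legacy = E_legacy$hartree,
    correction_mode = config$charge_correction,
    potential_corrected = pot_corrected, f_eps = f_eps), class = "energy_report")
  ## ---- record, profile, log
  settings <- list(method = config$method, cavity = config$cavity,
                   ndiv = config$ndiv, rsolv = config$rsolv,
                   mfactor = config$mfactor, screen = config$screen,
                   eps = config$eps,
                   charge_correction = config$charge_correction,
                   potcorr = config$potcorr, f_N = f_N, f_e = f_e)
  record <- structure(list(
    settings = settings,
    energies = list(E_gas = 0, E_solvated = E$hartree,
                    E_dielectric = E$hartree),
    geometry = geometry,
    segments = data.frame(index = seq_len(m), atom = segs$sphere,
                          x = segs$centers[, 1], y = segs$centers[, 2],
                          z = segs$centers[, 3], area = segs$areas,
                          charge = q_final, sigma = q_final / segs$areas,
                          potential = phi_used)), class = "cosmo_record")
  profile <- sigma_profile(segs, q_final)
  log <- list(n_spheres = nrow(cavity$spheres),
              n_aux_spheres = sum(is.na(cavity$spheres$atom)),
              n_segments = m, area = cavity$area, volume = cavity$volume,
              defect_before = defect_before, defect_after = defect_after,
              f_N = f_N, f_e = f_e, lambda = lambda, f_eps = f_eps,
              solver = sc$method,
              E_diel = E$hartree, E_diel_legacy = E_legacy$hartree)
  structure(list(energy = energy, record = record, profile = profile,
                 cavity = cavity,
                 charges = list(q = q_final, q_N = q_N_final,
                                q_e = q_e_final, f_eps = f_eps),
                 potentials = list(phi = pot$phi, phi_N = pot$phi_N,
                                   phi_e = pot$phi_e, phi_used = phi_used,
                                   phi_e_used = phi_e_used),
                 log = log, config = config),
            class = "cosmo_result")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("E_diel = %.8f Hartree (%.3f kcal/mol), correction = %s%s\n",
              x$E_diel, x$E_diel_kcal, x$correction_mode,
              if (x$potential_corrected) ", corrected potential" else ""))
  invisible(x)
}

#' @export
print.cosmo_result <- function(x, ...) {
  cat(sprintf("<cosmo_result> %d segments, defect %.2e -> %.2e e\n",
              x$log$n_segments, x$log$defect_before, x$log$defect_after))
  print(x$energy)
  invisible(x)
}
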