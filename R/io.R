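#' Read a particle table from CSV
#'
#' Expected schema: `particle_id`, `haul_id`, `category` (one of `line`,
#' `film`, `fragment`), `length_mm`, `width_mm` (may be empty for lines),
#' optional `height_mm`, optional `polymer` (`PE`, `PP`, `other`, `unknown`),
#' optional `mass_g`. Unknown columns are preserved.
#'
#' Length is the maximum and width the minimum Feret diameter, so
#' `length_mm >= width_mm` must hold where both are present. Rows violating
#' the ordering are handled according to `on_violation`: `"swap"` (default)
#' swaps the two values with a warning naming the rows (the two Feret
#' diameters are order statistics of the same measurement, so swapping
#' restores the definition), `"reject"` raises an error, `"none"` leaves them
#' untouched.
#'
#' @param path CSV file path.
#' @param on_violation how to treat rows with `length_mm < width_mm`.
#' @return A validated data.frame.
#' @export
read_particles <- function(path, on_violation = c("swap", "reject", "none")) {
  on_violation <- match.arg(on_violation)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_particles(tab, on_violation = on_violation)
}

#' Write a particle table to CSV
#'
#' Missing values (e.g. width of lines) are written as empty fields; a write
#' followed by [read_particles()] with `on_violation = "none"` is lossless.
#'
#' @param table particle data.frame.
#' @param path output CSV path.
#' @export
write_particles <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

# schema validation shared by read_particles() and the pipeline
validate_particles <- function(tab, on_violation = "swap") {
  required <- c("particle_id", "haul_id", "category", "length_mm", "width_mm")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(tab$length_mm) || !(is.numeric(tab$width_mm) || all(is.na(tab$width_mm))))
    stop("length_mm and width_mm must be numeric")
  # all-empty numeric columns come back from CSV as logical NA
  for (col in intersect(c("width_mm", "height_mm", "mass_g"), names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  bad_cat <- which(!tab$category %in% CATEGORIES)
  if (length(bad_cat))
    stop("unknown category in row(s): ", paste(utils::head(bad_cat, 10), collapse = ", "))
  no_width <- which(tab$category != "line" & is.na(tab$width_mm))
  if (length(no_width))
    stop("width_mm required for film/fragment; missing in row(s): ",
         paste(utils::head(no_width, 10), collapse = ", "))
  bad_len <- which(!is.finite(tab$length_mm) | tab$length_mm <= 0)
  if (length(bad_len))
    stop("nonpositive or missing length_mm in row(s): ",
         paste(utils::head(bad_len, 10), collapse = ", "))
  if ("polymer" %in% names(tab)) {
    tab$polymer[is.na(tab$polymer) | tab$polymer == ""] <- "unknown"
    bad_pol <- which(!tab$polymer %in% POLYMERS)
    if (length(bad_pol))
      stop("unknown polymer in row(s): ", paste(utils::head(bad_pol, 10), collapse = ", "))
  }
  swap <- which(!is.na(tab$width_mm) & tab$length_mm < tab$width_mm)
  if (length(swap) && on_violation != "none") {
    if (on_violation == "reject")
      stop("length_mm < width_mm in row(s): ", paste(utils::head(swap, 10), collapse = ", "))
    warning(sprintf("swapped length/width in %d row(s) (Feret max/min restored): %s",
                    length(swap), paste(utils::head(swap, 10), collapse = ", ")))
    l <- tab$length_mm[swap]
    tab$length_mm[swap] <- tab$width_mm[swap]
    tab$width_mm[swap] <- l
  }
  tab
}

#' Sampled water volume of a trawl haul
#'
#' The sampled volume is the product of trawl aperture width, sampled height
#' underwater and towed distance (all in metres), giving a volume in m^3.
#' Vectorized over hauls.
#'
#' @param trawl_width_m,sampled_height_m,distance_m positive reals (m).
#' @return Volume(s) in m^3.
#' @export
#' @examples
#' sample_volume(0.85, 0.10, 7000) # 595 m^3
sample_volume <- function(trawl_width_m, sampled_height_m, distance_m) {
  v <- cbind(trawl_width_m, sampled_height_m, distance_m)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all trawl dimensions must be positive")
  trawl_width_m * sampled_height_m * distance_m
}

#' Per-haul number and mass concentrations
#'
#' Counts particles (and sums their mass, when available) per haul and
#' divides by the haul's sampled volume. Hauls present in `hauls` but absent
#' from the particle table get zero concentrations. Concentrations are
#' reported per m^3 by default; `unit = "L"` divides by 1000.
#'
#' @param table particle data.frame (needs `haul_id`; `mass_g` optional).
#' @param hauls data.frame of haul metadata with columns `haul_id`,
#'   `trawl_width_m`, `sampled_height_m`, `distance_m`, optionally
#'   `total_mass_g` (used when the table has no `mass_g`).
#' @param unit `"m3"` (default) or `"L"`.
#' @return data.frame with per-haul counts, volume and concentrations.
#' @export
concentrations <- function(table, hauls, unit = c("m3", "L")) {
  unit <- match.arg(unit)
  vol <- sample_volume(hauls$trawl_width_m, hauls$sampled_height_m, hauls$distance_m)
  cnt <- table(factor(table$haul_id, levels = hauls$haul_id))
  mass <- if ("mass_g" %in% names(table)) {
    tapply(table$mass_g, factor(table$haul_id, levels = hauls$haul_id),
           sum, na.rm = TRUE)
  } else if ("total_mass_g" %in% names(hauls)) {
    hauls$total_mass_g
  } else {
    rep(NA_real_, nrow(hauls))
  }
  mass[is.na(mass)] <- if (all(is.na(mass))) NA_real_ else 0
  scale <- if (unit == "L") 1000 else 1
  out <- data.frame(
    haul_id = hauls$haul_id,
    n_particles = as.integer(cnt),
    mass_g = as.numeric(mass),
    volume_m3 = vol,
    stringsAsFactors = FALSE
  )
  out$number_conc <- out$n_particles / (vol * scale)
  out$mass_conc <- out$mass_g / (vol * scale)
  names(out)[names(out) == "number_conc"] <-
    if (unit == "L") "number_per_L" else "number_per_m3"
  names(out)[names(out) == "mass_conc"] <-
    if (unit == "L") "mass_g_per_L" else "mass_g_per_m3"
  out
}

#' Approximate line length from measured area
#'
#' Twisted lines cannot be measured end to end; their length is approximated
#' by dividing the measured area by the (roughly constant) line width.
#'
#' @param area_mm2 measured area (mm^2), positive.
#' @param width_mm line width (mm), positive.
#' @return Approximate length in mm.
#' @export
#' @examples
#' line_length_from_area(6.5, 0.65) # 10 mm
line_length_from_area <- function(area_mm2, width_mm) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0))
    stop("area_mm2 must be positive")
  if (any(!is.finite(width_mm)) || any(width_mm <= 0))
    stop("width_mm must be positive")
  area_mm2 / width_mm
}
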