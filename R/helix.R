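#' Radius-to-pitch ratio of an ideal protein-DNA helix
#'
#' When ssDNA of contour length `L` per nucleotide is helically wound around
#' a protein filament whose effective axial length is `L_prime` per
#' nucleotide, conservation of the ssDNA arc length per helical turn ties
#' the helix radius R and pitch rho together:
#' `R / rho = (1 / 2*pi) * sqrt((L / L_prime)^2 - 1)`.
#' `L_prime = L` corresponds to a straight (unwound) filament with infinite
#' pitch and ratio 0; `L_prime > L` is geometrically impossible.
#'
#' @param L Bare ssDNA contour length per nucleotide (nm/nt).
#' @param L_prime Effective contour length of the wound complex per
#'   nucleotide (nm/nt), in `(0, L]`.
#'
#' @return The dimensionless ratio R/rho.
#' @examples
#' radius_pitch_ratio(0.56, 0.41) # ~0.15
#' @export
radius_pitch_ratio <- function(L, L_prime) {
  if (!is.finite(L) || L <= 0) stop_domain("L must be positive")
  if (any(!is.finite(L_prime)) || any(L_prime <= 0)) {
    stop_domain("L_prime must be positive")
  }
  if (any(L_prime > L)) {
    stop_domain("L_prime > L: the wound complex cannot be longer than the bare ssDNA")
  }
  sqrt((L / L_prime)^2 - 1) / (2 * pi)
}

#' Derived structural parameters of an ideal SSB-ssDNA helical filament
#'
#' From the measured bare and complexed contour lengths per nucleotide and
#' the filament radius, derives the full set of ideal-helix descriptors:
#' the radius:pitch ratio, helical pitch, nucleotides of wound ssDNA per
#' turn, proteins per turn, inter-protein twist angle, occluded binding site
#' size, axial and arc length per protein, and protein densities.
#'
#' Two conventions for the number of proteins per turn are supported. In the
#' relaxed-filament convention (`h = NULL`) the occluded site size is fixed
#' at `bss_ref` nucleotides and `N = nt_per_turn / bss_ref`; the axial
#' length per protein follows as `(L_prime / L) * L * bss_ref`. In the axial
#' convention (`h` supplied) the protein's axial footprint is fixed and
#' `N = pitch / h`, so the site size shrinks as the filament unwinds:
#' `bss = h / L_prime`.
#'
#' A fully unwound filament (`L_prime = L`) is reported with an infinite
#' pitch sentinel and the defined limit values ratio = 0 and twist = 0.
#'
#' @param R Filament (helix) radius in nm.
#' @param L Bare ssDNA contour length per nucleotide (nm/nt).
#' @param L_prime Complex contour length per nucleotide (nm/nt), in `(0, L]`.
#' @param bss_ref Reference occluded site size in nt (default 7, the
#'   saturated gp32 footprint); used in the relaxed convention.
#' @param h Axial length per protein in nm, or `NULL` (default) for the
#'   relaxed convention.
#'
#' @return A list of class `helix_parameters`: `ratio`, `pitch` (nm),
#'   `nt_per_turn`, `proteins_per_turn`, `twist_per_protein` (degrees),
#'   `bss` (nt), `axial_per_protein` (nm), `arc_per_protein` (nm),
#'   `density_per_nm`, `density_per_nt`, `convention`, `infinite_pitch`,
#'   plus the inputs.
#' @examples
#' helix_parameters(R = 2.1, L = 0.56, L_prime = 0.41, bss_ref = 7)
#' @export
helix_parameters <- function(R, L, L_prime, bss_ref = 7, h = NULL) {
  if (!is.finite(R) || R <= 0) stop_domain("R must be positive")
  if (!is.finite(bss_ref) || bss_ref <= 0) stop_domain("bss_ref must be positive")
  if (!is.null(h) && (!is.finite(h) || h <= 0)) stop_domain("h must be positive")
  ratio <- radius_pitch_ratio(L, L_prime)

  infinite_pitch <- ratio == 0
  pitch <- if (infinite_pitch) Inf else R / ratio
  nt_per_turn <- pitch / L_prime
  arc_per_protein <- L * bss_ref
  if (is.null(h)) {
    convention <- "relaxed"
    axial_per_protein <- (L_prime / L) * arc_per_protein
    proteins_per_turn <- nt_per_turn / bss_ref
    bss <- bss_ref
  } else {
    convention <- "axial"
    axial_per_protein <- h
    proteins_per_turn <- pitch / h
    bss <- h / L_prime
    arc_per_protein <- L * bss
  }
  twist <- if (is.infinite(proteins_per_turn)) 0 else 360 / proteins_per_turn

  structure(list(
    ratio = ratio,
    pitch = pitch,
    nt_per_turn = nt_per_turn,
    proteins_per_turn = proteins_per_turn,
    twist_per_protein = twist,
    bss = bss,
    axial_per_protein = axial_per_protein,
    arc_per_protein = arc_per_protein,
    density_per_nm = 1 / axial_per_protein,
    density_per_nt = 1 / bss,
    convention = convention,
    infinite_pitch = infinite_pitch,
    inputs = list(R = R, L = L, L_prime = L_prime, bss_ref = bss_ref, h = h)
  ), class = "helix_parameters")
}

#' @export
print.helix_parameters <- function(x, ...) {
  cat(sprintf("ideal-helix filament parameters (%s convention):\n", x$convention))
  cat(sprintf("  R/pitch = %.3g, pitch = %.4g nm, %.3g nt/turn\n",
              x$ratio, x$pitch, x$nt_per_turn))
  cat(sprintf("  N = %.3g proteins/turn, twist = %.3g deg, bss = %.3g nt\n",
              x$proteins_per_turn, x$twist_per_protein, x$bss))
  cat(sprintf("  axial %.3g nm/protein, arc %.3g nm/protein\n",
              x$axial_per_protein, x$arc_per_protein))
  invisible(x)
}

## flatten a helix_parameters object to one data.frame row
helix_row <- function(hp) {
  data.frame(ratio = hp$ratio, pitch = hp$pitch,
             nt_per_turn = hp$nt_per_turn,
             proteins_per_turn = hp$proteins_per_turn,
             twist_per_protein = hp$twist_per_protein,
             bss = hp$bss,
             axial_per_protein = hp$axial_per_protein,
             arc_per_protein = hp$arc_per_protein,
             density_per_nm = hp$density_per_nm,
             density_per_nt = hp$density_per_nt)
}

#' Helix parameters across a concentration series
#'
#' Applies [helix_parameters()] at fixed radius `R` and fixed axial protein
#' length `h` (axial convention) to a table of complex contour lengths per
#' nucleotide measured at different free-protein concentrations, the machine
#' twin of the concentration sweep of filament geometry. As `L_prime` grows
#' toward `L` the pitch, proteins per turn and axial protein density
#' increase, while the twist angle and site size decrease.
#'
#' @param L_prime_table A data.frame with columns `concentration` (nM) and
#'   `L_prime` (nm/nt), every `L_prime` in `(0, L]`.
#' @param R Filament radius in nm (held constant across the sweep).
#' @param L Bare ssDNA contour length per nucleotide (nm/nt).
#' @param h Axial length per protein in nm (held constant).
#' @param bss_ref Reference site size in nt, used only for the arc length.
#'
#' @return A data.frame with one row per concentration: the concentration,
#'   `L_prime`, and all [helix_parameters()] columns.
#' @export
helix_sweep <- function(L_prime_table, R, L, h, bss_ref = 7) {
  stopifnot(is.data.frame(L_prime_table),
            all(c("concentration", "L_prime") %in% names(L_prime_table)))
  tab <- L_prime_table[order(L_prime_table$concentration), , drop = FALSE]
  if (is.unsorted(tab$L_prime) && is.unsorted(rev(tab$L_prime))) {
    warning("L_prime is not monotone in concentration; processed as-is")
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    hp <- helix_parameters(R = R, L = L, L_prime = tab$L_prime[i],
                           bss_ref = bss_ref, h = h)
    cbind(data.frame(concentration = tab$concentration[i],
                     L_prime = tab$L_prime[i]),
          helix_row(hp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filament radius from integrated AFM volumes
#'
#' Approximating both dsDNA and the protein-ssDNA filament as uniform
#' cylinders, the ratio of their AFM integrated volumes per unit length
#' yields the filament radius relative to the known dsDNA radius:
#' `r_ss = sqrt(V_ss * L_ds / (V_ds * L_ss)) * r_ds`.
#'
#' @param V_ss Integrated volume of the filament in nm^3.
#' @param L_ss Filament contour length in nm.
#' @param V_ds Integrated volume of the dsDNA reference in nm^3.
#' @param L_ds dsDNA reference length in nm; if `NULL`, computed as
#'   `n_bp * dsdna_rise` from `n_bp`.
#' @param r_ds dsDNA radius in nm (default from [sm_constants()]).
#' @param n_bp Length of the dsDNA reference in bp (used when `L_ds` is
#'   `NULL`).
#' @param constants A [sm_constants()] object.
#'
#' @return The filament radius `r_ss` in nm.
#' @export
filament_radius_from_volumes <- function(V_ss, L_ss, V_ds, L_ds = NULL,
                                         r_ds = NULL, n_bp = NULL,
                                         constants = sm_constants()) {
  r_ds <- r_ds %||% constants$dsdna_radius
  if (is.null(L_ds)) {
    if (is.null(n_bp)) stop_domain("supply L_ds or n_bp")
    L_ds <- n_bp * constants$dsdna_rise
  }
  vals <- c(V_ss = V_ss, L_ss = L_ss, V_ds = V_ds, L_ds = L_ds, r_ds = r_ds)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("all volumes, lengths and radii must be finite and positive")
  }
  sqrt(V_ss * L_ds / (V_ds * L_ss)) * r_ds
}

#' Protein turnover required at a moving replication fork
#'
#' During lagging-strand synthesis, SSB must vacate the template at the pace
#' of the polymerase. With a fork rate in nt/s and an occluded site size in
#' nt, `fork_rate / bss` proteins per second must dissociate from the
#' template; distributed over the `fragment_len / bss` proteins bound to an
#' Okazaki-fragment-sized template, the required per-protein dissociation
#' rate is `fork_rate / fragment_len`.
#'
#' @param fork_rate Replication fork rate in nt/s.
#' @param bss Occluded site size in nt.
#' @param fragment_len Template (Okazaki fragment) length in nt.
#'
#' @return A list with `proteins_per_s`, `per_protein_rate` (s^-1) and
#'   `proteins_per_fragment`.
#' @examples
#' turnover_requirement(500, 7, 2000)
#' @export
turnover_requirement <- function(fork_rate, bss, fragment_len) {
  vals <- c(fork_rate = fork_rate, bss = bss, fragment_len = fragment_len)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("fork_rate, bss and fragment_len must be positive")
  }
  list(proteins_per_s = fork_rate / bss,
       per_protein_rate = fork_rate / fragment_len,
       proteins_per_fragment = fragment_len / bss)
}
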