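#' Rate constants and mechanistic switches of the peroxidation scheme
#'
#' Bundles every rate constant of the inhibited-autoxidation reaction network
#' in SI units (M, s). Defaults describe methyl linoleate (MeLin) dispersed in
#' Triton X-100 micelles at 37 C: `k_p = 36` M^-1 s^-1 for propagation, an
#' essentially diffusion-limited `k_O2` for carbon-radical oxygenation, and a
#' peroxyl self-termination `two_kt` calibrated so that the uninhibited rate
#' at R_i of a few nM/s matches the observed uninhibited uptake (about
#' 550 nM/s); `two_kt` is a calibration, not a literature value.
#'
#' @param k_p Propagation rate constant, LOO. + LH (M^-1 s^-1).
#' @param k_O2 L. + O2 addition rate constant (M^-1 s^-1). Only used for the
#'   warning check: the carbon radical is not an explicit state because
#'   oxygenation is orders of magnitude faster than any other step.
#' @param two_kt Peroxyl self-termination constant 2k_t (M^-1 s^-1), expressed
#'   so that d[LOO.]/dt = -two_kt [LOO.]^2.
#' @param k_rad_cross Phenoxyl + peroxyl cross-termination (M^-1 s^-1).
#' @param two_k_AO Phenoxyl self-decay constant 2k_TO (M^-1 s^-1), same
#'   convention as `two_kt`. 15 M^-1 s^-1 is the cationic-micelle value for
#'   the tocopheroxyl radical; it is ~5.9e3 in benzene.
#' @param k_r Regeneration rate constant, phenoxyl of a `regenerable`
#'   antioxidant + co-antioxidant phenol (M^-1 s^-1). 0 disables regeneration.
#' @param k_dim Phenoxyl-phenoxyl coupling constant for `dimerizes`
#'   antioxidants (M^-1 s^-1), convention d[ArO.]/dt = -k_dim [ArO.]^2.
#' @param k_dec First-order antioxidant decomposition (s^-1); qualitative
#'   stand-in for base-catalysed degradation at alkaline pH.
#' @param include_initiator_O2 Add the initiation flux R_i to the O2 ledger
#'   (oxygen consumed making the initiator-derived peroxyl radicals).
#'
#' @return An object of class `reaction_parameters`.
#' @export
reaction_parameters <- function(k_p = 36,
                                k_O2 = 1e9,
                                two_kt = 150,
                                k_rad_cross = 1e8,
                                two_k_AO = 15,
                                k_r = 0,
                                k_dim = 0,
                                k_dec = 0,
                                include_initiator_O2 = FALSE) {
  p <- list(k_p = k_p, k_O2 = k_O2, two_kt = two_kt,
            k_rad_cross = k_rad_cross, two_k_AO = two_k_AO,
            k_r = k_r, k_dim = k_dim, k_dec = k_dec,
            include_initiator_O2 = isTRUE(include_initiator_O2))
  ks <- unlist(p[c("k_p", "k_O2", "two_kt", "k_rad_cross", "two_k_AO",
                   "k_r", "k_dim", "k_dec")])
  if (any(!is.finite(ks)) || any(ks < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  if (k_O2 < 1e3 * k_p) {
    warning("k_O2 < 1000 * k_p: the fast-oxygenation approximation ",
            "(no explicit carbon radical) may not hold", call. = FALSE)
  }
  structure(p, class = "reaction_parameters")
}

#' Specification of one phenolic antioxidant
#'
#' @param name Identifier (e.g. `"PMHC"`, `"RSV"`).
#' @param conc0 Initial concentration at injection (M).
#' @param k_inh Inhibition rate constant for H transfer to LOO. (M^-1 s^-1).
#' @param dimerizes If `TRUE`, the phenoxyl radical couples (rate `k_dim`) to
#'   a dimer whose recovered hydroxyls can trap further peroxyl radicals.
#' @param dimer_k_inh Inhibition rate constant of the dimer phenols
#'   (M^-1 s^-1); 0 makes the coupling product inert.
#' @param cascade_depth Number of trapping-competent coupling generations to
#'   instantiate as explicit species (>= 0). Radicals of the last generation
#'   still couple, but to an inert product.
#' @param regenerable If `TRUE`, this species' phenoxyl is reduced back to
#'   the phenol by every other (non-radical) antioxidant in the roster at
#'   rate `k_r` (the tocopherol-analogue role in synergy).
#'
#' @return An object of class `antioxidant_spec`.
#' @export
antioxidant <- function(name, conc0, k_inh,
                        dimerizes = FALSE, dimer_k_inh = 0,
                        cascade_depth = 0L, regenerable = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(conc0) || conc0 < 0) stop("conc0 must be >= 0", call. = FALSE)
  if (!is.finite(k_inh) || k_inh <= 0) stop("k_inh must be > 0", call. = FALSE)
  cascade_depth <- as.integer(cascade_depth)
  if (cascade_depth < 0L) stop("cascade_depth must be >= 0", call. = FALSE)
  if (!isTRUE(dimerizes) && cascade_depth != 0L) {
    stop("cascade_depth must be 0 when dimerizes is FALSE", call. = FALSE)
  }
  if (!is.finite(dimer_k_inh) || dimer_k_inh < 0) {
    stop("dimer_k_inh must be >= 0", call. = FALSE)
  }
  structure(list(name = name, conc0 = conc0, k_inh = k_inh,
                 dimerizes = isTRUE(dimerizes), dimer_k_inh = dimer_k_inh,
                 cascade_depth = cascade_depth,
                 regenerable = isTRUE(regenerable)),
            class = "antioxidant_spec")
}

#' One peroxidation run: medium, concentrations, initiation, antioxidants
#'
#' @param medium `"micelle"` or `"liposome"`; a label carried through to the
#'   metrics tables (it has no mechanistic effect beyond the defaults chosen
#'   by the convenience constructors).
#' @param pH_label Numeric pH tag. A label only: no ionisation model.
#' @param LH0 Oxidizable lipid concentration (M); 2.74e-3 is the MeLin loading
#'   used in both media.
#' @param O2_0 Initial dissolved O2 (M); 1.0e-3 approximates an O2-saturated
#'   aqueous buffer near 37 C.
#' @param R_i Radical initiation flux (M s^-1), the empirical zeroth-order
#'   rate at which the azo-initiator delivers peroxyl radicals to the lipid.
#' @param antioxidants List of [antioxidant()] specs (possibly empty).
#' @param O2_clamped If `TRUE` (default) dissolved O2 is treated as
#'   non-limiting: runs are stopped experimentally at <= 20% depletion.
#'
#' @return An object of class `experiment_system`.
#' @export
experiment_system <- function(medium = c("micelle", "liposome"),
                              pH_label = 7,
                              LH0 = 2.74e-3,
                              O2_0 = 1.0e-3,
                              R_i = 4.6e-9,
                              antioxidants = list(),
                              O2_clamped = TRUE) {
  medium <- match.arg(medium)
  if (!is.finite(LH0) || LH0 <= 0) stop("LH0 must be > 0", call. = FALSE)
  if (!is.finite(R_i) || R_i < 0) stop("R_i must be >= 0", call. = FALSE)
  if (!isTRUE(O2_clamped) && (!is.finite(O2_0) || O2_0 <= 0)) {
    stop("O2_0 must be > 0 when O2 is not clamped", call. = FALSE)
  }
  if (inherits(antioxidants, "antioxidant_spec")) {
    antioxidants <- list(antioxidants)
  }
  if (!all(vapply(antioxidants, inherits, logical(1), "antioxidant_spec"))) {
    stop("antioxidants must be a list of antioxidant() specs", call. = FALSE)
  }
  nm <- vapply(antioxidants, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate antioxidant names", call. = FALSE)
  structure(list(medium = medium, pH_label = pH_label, LH0 = LH0,
                 O2_0 = O2_0, R_i = R_i, antioxidants = antioxidants,
                 O2_clamped = isTRUE(O2_clamped)),
            class = "experiment_system")
}

#' Convenience systems for the two studied media
#'
#' `micelle_system()` is 2.74 mM MeLin in 8 mM Triton X-100 (k_p = 36);
#' `liposome_system()` is 2.74 mM MeLin in 20.2 mM DMPC vesicles (k_p = 41).
#' Initiation-flux defaults sit inside the empirically observed ranges
#' (4.4-5.7 nM/s micellar, 2.3-3.8 nM/s liposomal at 10 mM initiator).
#'
#' @inheritParams experiment_system
#' @return An `experiment_system`.
#' @export
micelle_system <- function(pH_label = 7, R_i = 4.6e-9,
                           antioxidants = list(), ...) {
  experiment_system(medium = "micelle", pH_label = pH_label, R_i = R_i,
                    antioxidants = antioxidants, ...)
}

#' @rdname micelle_system
#' @export
liposome_system <- function(pH_label = 7, R_i = 2.3e-9,
                            antioxidants = list(), ...) {
  experiment_system(medium = "liposome", pH_label = pH_label, R_i = R_i,
                    antioxidants = antioxidants, ...)
}

#' Propagation rate constant for the medium
#'
#' 36 M^-1 s^-1 for MeLin in Triton X-100 micelles, 41 M^-1 s^-1 in DMPC
#' liposomes.
#'
#' @param medium `"micelle"` or `"liposome"` (or an `experiment_system`).
#' @return k_p in M^-1 s^-1.
#' @export
kp_for_medium <- function(medium) {
  if (inherits(medium, "experiment_system")) medium <- medium$medium
  switch(match.arg(medium, c("micelle", "liposome")),
         micelle = 36, liposome = 41)
}

#' @export
print.experiment_system <- function(x, ...) {
  cat(sprintf("<experiment_system> %s, pH %s, LH0 %.3g M, R_i %.3g M/s\n",
              x$medium, format(x$pH_label), x$LH0, x$R_i))
  for (a in x$antioxidants) {
    cat(sprintf("  %s: %.3g M, k_inh %.3g%s%s\n", a$name, a$conc0, a$k_inh,
                if (a$dimerizes) sprintf(", dimerizes (depth %d, k_inh,dim %.3g)",
                                         a$cascade_depth, a$dimer_k_inh) else "",
                if (a$regenerable) ", regenerable" else ""))
  }
  invisible(x)
}
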