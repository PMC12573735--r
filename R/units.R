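#' Unit conversion constants
#'
#' All geometry is carried in Angstrom, pressures in GPa, forces in nN and
#' energies in kcal/mol. The two bridges between these unit systems are
#' defined once here and used everywhere:
#'
#' * `gpa_angstrom2_to_nn`: 1 GPa acting on 1 Angstrom^2 is
#'   \eqn{10^9 \mathrm{Pa} \times 10^{-20} \mathrm{m}^2 = 10^{-11}} N
#'   = 0.01 nN.
#' * `nn_angstrom_to_kcal_mol`: 1 nN Angstrom is \eqn{10^{-19}} J per
#'   molecule; multiplying by the Avogadro constant (CODATA,
#'   6.02214076e23 1/mol) and dividing by the thermochemical calorie
#'   (4184 J/kcal) gives 14.3933 kcal/mol (6 significant figures).
#'
#' @format Named numeric constants.
#' @name units
NULL

#' @rdname units
#' @export
gpa_angstrom2_to_nn <- 0.01

#' @rdname units
#' @export
nn_angstrom_to_kcal_mol <- 1e-19 * 6.02214076e23 / 4184
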