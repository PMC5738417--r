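#' Per-cell force in the compressive loading assay
#'
#' Converts the mass placed on a cell monolayer into the compressive force
#' experienced by each cell: the applied weight minus the buoyant force of
#' the displaced medium, divided by the number of cells,
#' `force/cell = (m_total - m_buoyant) * 1e-3 * g / n_cells`,
#' reported in micronewtons. With the default `g = 10` m/s^2, a 22 g load
#' with a 1.1 g buoyancy-equivalent submerged mass over 1000 cells gives
#' 209 uN per cell.
#'
#' @param total_mass_g Total applied mass, grams.
#' @param buoyant_equivalent_mass_g Mass equivalent of the buoyant force on
#'   the submerged part of the load, grams (`<= total_mass_g`).
#' @param n_cells Number of cells sharing the load (>= 1).
#' @param g Gravitational acceleration, m/s^2 (default 10; use 9.81 for the
#'   conventional value).
#' @return Force per cell in micronewtons.
#' @examples
#' force_per_cell(22, 1.1, 1000)  # 209
#' @export
force_per_cell <- function(total_mass_g, buoyant_equivalent_mass_g = 0,
                           n_cells = 1, g = 10) {
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  if (total_mass_g < 0 || buoyant_equivalent_mass_g < 0) {
    abort("masses must be non-negative")
  }
  if (buoyant_equivalent_mass_g > total_mass_g) {
    abort("buoyant-equivalent mass cannot exceed the total mass")
  }
  force_n <- (total_mass_g - buoyant_equivalent_mass_g) * 1e-3 * g
  force_n / n_cells * 1e6
}
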