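# Shared fixtures: tiny record tables and analytic image masks built in code.

make_record <- function(cell_id = "c1", cohort = "HbAS", subgroup = 1L,
                        free_rmax = 5, free_rmin = 4.8,
                        trapped_rmax = 4.5, trapped_rmin = 4.3,
                        stretched_rmax = 5.5, stretched_rmin = 4.3,
                        trap_force = 0.3, drag_force = 1.2,
                        speed = 20) {
  data.frame(
    cell_id = cell_id, cohort = cohort, subgroup = subgroup,
    stage_speed_um_s = speed,
    trap_force_pN = trap_force, drag_force_pN = drag_force,
    free_rmax_um = free_rmax, free_rmin_um = free_rmin,
    free_area_um2 = pi * free_rmax * free_rmin,
    trapped_rmax_um = trapped_rmax, trapped_rmin_um = trapped_rmin,
    trapped_area_um2 = pi * trapped_rmax * trapped_rmin,
    stretched_rmax_um = stretched_rmax, stretched_rmin_um = stretched_rmin,
    stretched_area_um2 = pi * stretched_rmax * stretched_rmin,
    stringsAsFactors = FALSE)
}

make_records <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i)
    make_record(cell_id = sprintf("c%02d", i), ...)))
}

# analytic pixel-counted disc mask (no rendering involved)
disc_mask <- function(radius_px, side = 2L * ceiling(radius_px) + 11L) {
  ctr <- (side + 1) / 2
  x <- matrix(seq_len(side) - ctr, side, side, byrow = TRUE)
  y <- matrix(seq_len(side) - ctr, side, side)
  x^2 + y^2 <= radius_px^2
}

# all permutations of seq_len(n), for small n
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}
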