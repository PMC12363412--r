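# Multi-optode combinations reported per arrangement, after removing the
# symmetry-equivalent ones (LINR/TRAP: 1A == 2B, 1B == 2A, 1AB == 2AB,
# 12A == 12B; DRCT: any single optode equivalent, 12 == AB, all triples
# equivalent; ALIN has no symmetry so every combination is listed).
multi_optode_combos <- function(name) {
  lin <- list(c("1", "A"), c("1", "B"), c("1", "2"), c("A", "B"),
              c("1", "A", "B"), c("1", "2", "A"), c("1", "2", "A", "B"))
  switch(name,
    LINR = lin,
    TRAP = lin,
    ALIN = list(c("1", "A"), c("1", "B"), c("2", "A"), c("2", "B"),
                c("1", "2"), c("A", "B"), c("1", "A", "B"),
                c("2", "A", "B"), c("1", "2", "A"), c("1", "2", "B"),
                c("1", "2", "A", "B")),
    DRCT = list(c("1", "A"), c("1", "B"), c("1", "2"), c("1", "A", "B"),
                c("1", "2", "A", "B")),
    stop("unknown arrangement: ", name))
}

recovery_errors <- function(rho, medium, inst) {
  arrless <- new_reflectance_set(complex_reflectance(rho, medium, inst),
                                 rho, medium, inst)
  out <- list()
  for (method in c("slopes", "iterative")) {
    fit <- if (method == "iterative") fit_iterative(arrless, rho, inst)
           else fit_slopes(arrless, rho, inst)
    out[[method]] <- c(err_mua = 100 * (fit$mua - medium$mua) / medium$mua,
                       err_musp = 100 * (fit$musp - medium$musp) /
                         medium$musp)
  }
  out
}

#' Reproduce one of the study's report tables
#'
#' Regenerates, from scratch, the rows of one of the six report tables:
#'
#' * `T1` - accuracy of the slopes versus iterative method at correct
#'   distances, over the 3 x 3 property grid and both distance sets
#'   (`[25,25,37,37]` and `[20,30,32,42]` mm).
#' * `T2` - LINR circle-orbit RMS errors for single-optode 1 mm
#'   displacement, both methods, over the property grid.
#' * `T3`, `T4`, `T5` - the same for ALIN, TRAP, and DRCT (iterative
#'   method), with only symmetry-distinct optodes listed.
#' * `T6` - multi-optode co-displacement at `mua = 0.01`, `musp = 1.0`
#'   1/mm for all four arrangements (iterative method).
#'
#' Columns `*_pct` carry full precision; `*_printed` are rounded to the two
#' significant figures used in the printed tables.
#'
#' @param table_id One of `"T1"` ... `"T6"`.
#' @param inst An [fd_instrument()].
#' @param trap_b TRAP detector separation (mm); see [ds_arrangement()].
#' @param n_angles,mc_samples,seed Sampling controls passed to
#'   [sigma_circle()]. With the same seed, Monte Carlo rows reproduce
#'   bit-identically.
#' @param out_csv Optional path; if given, the table is also written as CSV.
#' @return A data frame, one row per table cell.
#' @export
run_table <- function(table_id = c("T1", "T2", "T3", "T4", "T5", "T6"),
                      inst = fd_instrument(), trap_b = trap_right_angle_b(),
                      n_angles = 72L, mc_samples = 4096L, seed = 1L,
                      out_csv = NULL) {
  table_id <- match.arg(table_id)
  grid <- study_grid()
  tab <- switch(table_id,
    T1 = {
      rho_sets <- list("25,25,37,37" = c(25, 25, 37, 37),
                       "20,30,32,42" = c(20, 30, 32, 42))
      do.call(rbind, lapply(names(rho_sets), function(rs) {
        do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
          med <- ds_medium(grid$mua[g], grid$musp[g])
          e <- recovery_errors(stats::setNames(rho_sets[[rs]], PAIR_NAMES),
                               med, inst)
          data.frame(rho_set = rs, mua = med$mua, musp = med$musp,
                     slopes_err_mua_pct = e$slopes[["err_mua"]],
                     slopes_err_musp_pct = e$slopes[["err_musp"]],
                     iterative_err_mua_pct = e$iterative[["err_mua"]],
                     iterative_err_musp_pct = e$iterative[["err_musp"]])
        }))
      }))
    },
    T2 = {
      arr <- ds_arrangement("LINR")
      do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
        med <- ds_medium(grid$mua[g], grid$musp[g])
        do.call(rbind, lapply(c("1", "A"), function(op) {
          row <- data.frame(mua = med$mua, musp = med$musp,
                            optode = if (op == "1") "1 or 2" else "A or B")
          for (method in c("slopes", "iterative")) {
            s <- sigma_circle(arr, op, med, inst, method = method,
                              n_angles = n_angles)
            row[[paste0(method, "_sigma_mua_pct")]] <- s$sigma_mua_rel
            row[[paste0(method, "_sigma_musp_pct")]] <- s$sigma_musp_rel
          }
          row
        }))
      }))
    },
    T3 = single_optode_table(ds_arrangement("ALIN"),
                             c("1", "2", "A", "B"), grid, inst, n_angles),
    T4 = single_optode_table(ds_arrangement("TRAP", trap_b = trap_b),
                             c("1", "A"), grid, inst, n_angles,
                             labels = c("1 or 2", "A or B")),
    T5 = single_optode_table(ds_arrangement("DRCT"), "1", grid, inst,
                             n_angles, labels = "1, 2, A, or B"),
    T6 = {
      med <- ds_medium(0.010, 1.0)
      arrs <- list(LINR = ds_arrangement("LINR"),
                   ALIN = ds_arrangement("ALIN"),
                   TRAP = ds_arrangement("TRAP", trap_b = trap_b),
                   DRCT = ds_arrangement("DRCT"))
      do.call(rbind, lapply(names(arrs), function(nm) {
        combos <- multi_optode_combos(nm)
        do.call(rbind, lapply(combos, function(ops) {
          s <- sigma_circle(arrs[[nm]], ops, med, inst,
                            n_angles = n_angles, mc_samples = mc_samples,
                            seed = seed)
          data.frame(arrangement = nm,
                     optodes = paste(ops, collapse = ","),
                     sigma_mua_pct = s$sigma_mua_rel,
                     sigma_musp_pct = s$sigma_musp_rel,
                     n_samples = s$n_samples, sampling = s$sampling)
        }))
      }))
    })
  for (col in grep("_pct$", names(tab), value = TRUE))
    tab[[sub("_pct$", "_printed", col)]] <- signif(tab[[col]], 2)
  rownames(tab) <- NULL
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}

single_optode_table <- function(arr, optodes, grid, inst, n_angles,
                                labels = optodes) {
  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    med <- ds_medium(grid$mua[g], grid$musp[g])
    do.call(rbind, lapply(seq_along(optodes), function(k) {
      s <- sigma_circle(arr, optodes[k], med, inst, n_angles = n_angles)
      data.frame(mua = med$mua, musp = med$musp, optode = labels[k],
                 sigma_mua_pct = s$sigma_mua_rel,
                 sigma_musp_pct = s$sigma_musp_rel)
    }))
  }))
}

#' Generate displacement error maps for an arrangement
#'
#' Thin orchestration over [sweep_square()]: one map per optode and
#' quantity, optionally written as CSV (deterministic output, so re-running
#' with the same inputs reproduces the files exactly).
#'
#' @param arr A nominal `ds_arrangement`.
#' @param optodes Optodes to displace.
#' @param quantities Quantities to map (see [sweep_square()]).
#' @param medium True [ds_medium()].
#' @param inst An [fd_instrument()].
#' @param method,halfwidth,step,delta_mua Passed to [sweep_square()].
#' @param out_dir Optional directory for CSV output, one file per map,
#'   named `map_<arrangement>_<optode>_<quantity>_<method>.csv`.
#' @return Nested list of `error_map`s indexed `[[optode]][[quantity]]`.
#' @export
run_maps <- function(arr, optodes, quantities, medium,
                     inst = fd_instrument(),
                     method = "iterative", halfwidth = 10, step = 0.5,
                     delta_mua = 1e-4, out_dir = NULL) {
  out <- lapply(optodes, function(op) {
    maps <- lapply(quantities, function(q) {
      m <- sweep_square(arr, op, q, medium, inst, method = method,
                        halfwidth = halfwidth, step = step,
                        delta_mua = delta_mua)
      if (!is.null(out_dir)) {
        write_error_map(m, file.path(out_dir, sprintf(
          "map_%s_%s_%s_%s.csv", arr$name, op, q, method)))
      }
      m
    })
    stats::setNames(maps, quantities)
  })
  stats::setNames(out, optodes)
}
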