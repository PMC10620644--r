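## Minima and barriers on a binned free-energy landscape.

# 8-connected neighbors of (i, j) on an nr x nc grid, as index pairs
neighbors8 <- function(i, j, nr, nc) {
  di <- rep(-1:1, times = 3)
  dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ni <- i + di[keep]
  nj <- j + dj[keep]
  ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
  cbind(ni[ok], nj[ok])
}

#' Minimax (mountain-pass) path value between two bins
#'
#' The lowest possible "highest point" over all 8-connected paths of active
#' (non-`NA`) bins between `from` and `to`: a Dijkstra variant where a
#' path's cost is the maximum bin value along it (endpoints included).
#' This is the discrete saddle height between two minima.
#'
#' @param m numeric matrix (`NA` = inactive bin).
#' @param from,to length-2 integer bin indices `(row, col)`.
#' @return the minimax path height, or `Inf` when no active path exists.
#' @export
minimax_path_height <- function(m, from, to) {
  nr <- nrow(m); nc <- ncol(m)
  if (is.na(m[from[1], from[2]]) || is.na(m[to[1], to[2]])) return(Inf)
  best <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  best[from[1], from[2]] <- m[from[1], from[2]]
  repeat {
    idx <- which(!done & is.finite(best))
    if (!length(idx)) return(Inf)
    cur <- idx[which.min(best[idx])]
    ci <- ((cur - 1) %% nr) + 1
    cj <- ((cur - 1) %/% nr) + 1
    if (ci == to[1] && cj == to[2]) return(best[ci, cj])
    done[ci, cj] <- TRUE
    nb <- neighbors8(ci, cj, nr, nc)
    for (k in seq_len(nrow(nb))) {
      ni <- nb[k, 1]; nj <- nb[k, 2]
      if (done[ni, nj] || is.na(m[ni, nj])) next
      cand <- max(best[ci, cj], m[ni, nj])
      if (cand < best[ni, nj]) best[ni, nj] <- cand
    }
  }
}

#' Minima and escape barriers of a 2D free-energy landscape
#'
#' The global minimum (GM) is the active bin of lowest free energy (ties
#' broken by lowest bin index, column-major). Local minima (LM) are active
#' bins that are strictly below all of their 8-connected active neighbors,
#' have at least one active neighbor (isolated single-visit bins are not
#' minima), lie below the free-energy cap `lm_cap`, and are not the GM. The
#' escape barrier of each LM towards the GM is the minimax path height from
#' LM to GM minus the LM free energy. Strict minima whose barrier falls
#' below `min_prominence` are discarded as sampling noise: k_B T-scale
#' corrugation is within the estimation error of moderately sampled bins
#' and does not indicate a metastable state. Each minimum is flagged apical
#' when its bin center satisfies the apical-zone criteria.
#'
#' @param fel a [fel_from_msm()] result.
#' @param apical an [apical_criteria()] used to flag minima.
#' @param lm_cap report only local minima with `F <= lm_cap` (k_B T). The
#'   default of 4 keeps genuine metastable basins while ignoring shallow
#'   noise minima high up the landscape.
#' @param min_prominence minimum escape barrier (k_B T) for a local minimum
#'   to count as metastable.
#' @return list of class `minima_report`: `gm` (one-row data.frame with bin
#'   indices, centers, `F_kbt`, `apical`) and `lm` (data.frame, possibly
#'   empty, with additionally `barrier_kbt`).
#' @export
find_minima_and_barrier <- function(fel, apical = apical_criteria(),
                                    lm_cap = 4, min_prominence = 2) {
  m <- fel$matrix
  nr <- nrow(m); nc <- ncol(m)
  active <- which(!is.na(m))
  if (!length(active)) stop("no active bins in FEL")
  gm_idx <- active[m[active] == min(m[active])][1]
  gi <- ((gm_idx - 1) %% nr) + 1
  gj <- ((gm_idx - 1) %/% nr) + 1

  describe <- function(i, j) {
    wd <- diff(fel$grid$d_range) / fel$grid$n_d
    wt <- diff(fel$grid$theta_range) / fel$grid$n_theta
    dc <- fel$grid$d_range[1] + (i - 0.5) * wd
    tc <- fel$grid$theta_range[1] + (j - 0.5) * wt
    data.frame(bin_d = i, bin_theta = j, d_center = dc, theta_center = tc,
               F_kbt = m[i, j],
               apical = classify_apical(dc, tc, apical))
  }

  lm_rows <- list()
  for (idx in active) {
    if (idx == gm_idx) next
    i <- ((idx - 1) %% nr) + 1
    j <- ((idx - 1) %/% nr) + 1
    if (m[i, j] > lm_cap) next
    nb <- neighbors8(i, j, nr, nc)
    nvals <- m[nb]
    nvals <- nvals[!is.na(nvals)]
    if (!length(nvals)) next          # isolated bin: not a minimum
    if (all(m[i, j] < nvals)) {
      row <- describe(i, j)
      row$barrier_kbt <- minimax_path_height(m, c(i, j), c(gi, gj)) - m[i, j]
      if (row$barrier_kbt >= min_prominence) {
        lm_rows[[length(lm_rows) + 1L]] <- row
      }
    }
  }
  lm <- if (length(lm_rows)) do.call(rbind, lm_rows) else
    describe(gi, gj)[0, ]
  if (nrow(lm)) lm <- lm[order(lm$F_kbt), ]
  rownames(lm) <- NULL
  structure(list(gm = describe(gi, gj), lm = lm), class = "minima_report")
}

#' @export
print.minima_report <- function(x, ...) {
  cat(sprintf("GM: bin (%d, %d), F = %.2f k_BT, %s\n",
              x$gm$bin_d, x$gm$bin_theta, x$gm$F_kbt,
              if (x$gm$apical) "apical" else "side"))
  if (nrow(x$lm) == 0) {
    cat("no local minima\n")
  } else {
    for (k in seq_len(nrow(x$lm))) {
      cat(sprintf("LM: bin (%d, %d), F = %.2f k_BT, barrier %.2f k_BT, %s\n",
                  x$lm$bin_d[k], x$lm$bin_theta[k], x$lm$F_kbt[k],
                  x$lm$barrier_kbt[k],
                  if (x$lm$apical[k]) "apical" else "side"))
    }
  }
  invisible(x)
}

#' Plot a 2D free-energy landscape
#'
#' Heat map of the binned free energy over (d, theta) with the apical zone
#' and any minima annotated.
#'
#' @param fel a [fel_from_msm()] result.
#' @param minima optional [find_minima_and_barrier()] report to annotate.
#' @param apical an [apical_criteria()]; its theta zone is drawn.
#' @param ... passed to [graphics::image()].
#' @export
plot_fel <- function(fel, minima = NULL, apical = apical_criteria(), ...) {
  g <- fel$grid
  dc <- g$d_range[1] + (seq_len(g$n_d) - 0.5) * diff(g$d_range) / g$n_d
  tc <- g$theta_range[1] +
    (seq_len(g$n_theta) - 0.5) * diff(g$theta_range) / g$n_theta
  graphics::image(dc, tc, fel$matrix,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = "d_OP (Å)", ylab = expression(theta[OPO]),
                  ...)
  graphics::abline(h = c(apical$theta_min, apical$theta_max),
                   col = "darkgreen", lty = 2)
  if (!is.null(minima)) {
    graphics::points(minima$gm$d_center, minima$gm$theta_center, pch = 8,
                     cex = 1.5)
    if (nrow(minima$lm)) {
      graphics::points(minima$lm$d_center, minima$lm$theta_center, pch = 1,
                       cex = 1.5)
    }
  }
  invisible(fel)
}
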