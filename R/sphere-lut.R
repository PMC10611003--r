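# Forward model of integrating-sphere observables and the look-up-table
# inversion recovering (mus', mua) from measured total hemispherical
# transmittance and reflectance.

#' Total hemispherical transmittance and reflectance of a slab
#'
#' Simulated counterpart of a calibrated integrating-sphere measurement:
#' the fractions of unit incident power leaving through the lower (T) and
#' upper (R) hemisphere, including the ballistic/specular components.
#'
#' @param slab an [optical_slab()].
#' @param engine `"pn"` (deterministic P_N solve, default) or `"mc"`
#'   (Monte Carlo).
#' @param budget for `engine = "pn"` the odd P_N order (default 31); for
#'   `engine = "mc"` the photon count (default 1e6).
#' @param seed RNG seed, required for the `mc` engine.
#' @return Named numeric vector `c(T = ..., R = ...)`.
#' @export
forward_tr <- function(slab, engine = c("pn", "mc"), budget = NULL,
                       seed = NULL) {
  engine <- match.arg(engine)
  if (engine == "pn") {
    order <- if (is.null(budget)) 31L else as.integer(budget)
    sol <- solve_pn(slab, order)
    fl <- pn_hemispheric_fluxes(sol)
    c(T = fl$t_total, R = fl$r_total)
  } else {
    if (is.null(seed)) stop("the 'mc' engine requires an explicit 'seed'")
    n <- if (is.null(budget)) 1e6 else budget
    m <- mc_simulate(slab, n, seed = seed)
    c(T = m$t_total, R = m$r_total)
  }
}

#' Build a look-up table of sphere observables over (mus', mua)
#'
#' Evaluates the forward model node-by-node on the tensor grid
#' `mus_prime_axis` x `mua_axis` at fixed anisotropy, refractive indices and
#' thickness, storing total hemispherical T and R. The table is the forward
#' surface inverted by [lut_invert()].
#'
#' @param mus_prime_axis strictly increasing grid of mus' values (1/mm),
#'   >= 2 nodes.
#' @param mua_axis strictly increasing grid of mua values (1/mm), >= 2
#'   nodes (a log-spaced axis is recommended; interpolation is performed on
#'   log10 mua).
#' @param d slab thickness (mm).
#' @param g anisotropy (default 0.6).
#' @param n_slab,n_ambient refractive indices.
#' @param engine,budget,seed forwarded to [forward_tr()]; the same seed
#'   stream makes MC-built tables bit-reproducible.
#' @return Object of class `lookup_table` with matrices `table_T`,
#'   `table_R` (rows = mus', cols = mua), the axes, the fixed parameters
#'   and a provenance record.
#' @export
build_lut <- function(mus_prime_axis, mua_axis, d, g = 0.6,
                      n_slab = 1.552, n_ambient = 1.0,
                      engine = c("pn", "mc"), budget = NULL, seed = 1L) {
  engine <- match.arg(engine)
  if (length(mus_prime_axis) < 2L || length(mua_axis) < 2L)
    stop("each LUT axis needs at least 2 nodes")
  if (any(diff(mus_prime_axis) <= 0) || any(diff(mua_axis) <= 0))
    stop("LUT axes must be strictly increasing")
  if (any(mua_axis <= 0)) stop("'mua_axis' must be positive (log grid)")
  nT <- matrix(NA_real_, length(mus_prime_axis), length(mua_axis))
  nR <- nT
  for (i in seq_along(mus_prime_axis)) {
    for (j in seq_along(mua_axis)) {
      slab <- optical_slab(d = d, mus_prime = mus_prime_axis[i],
                           mua = mua_axis[j], g = g,
                           n_slab = n_slab, n_ambient = n_ambient)
      tr <- forward_tr(slab, engine = engine, budget = budget,
                       seed = if (engine == "mc")
                         seed + i * 1000L + j else NULL)
      nT[i, j] <- tr[["T"]]; nR[i, j] <- tr[["R"]]
    }
  }
  structure(list(
    grid_mus_prime = mus_prime_axis, grid_mua = mua_axis,
    fixed = list(g = g, n_slab = n_slab, n_ambient = n_ambient, d = d),
    table_T = nT, table_R = nR,
    provenance = list(engine = engine, budget = budget, seed = seed)
  ), class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("lookup_table: %d x %d nodes, mus' [%g, %g] /mm, mua [%g, %g] /mm\n",
              length(x$grid_mus_prime), length(x$grid_mua),
              min(x$grid_mus_prime), max(x$grid_mus_prime),
              min(x$grid_mua), max(x$grid_mua)))
  cat(sprintf("  fixed: g = %g, n = %g/%g, d = %g mm | engine %s\n",
              x$fixed$g, x$fixed$n_slab, x$fixed$n_ambient, x$fixed$d,
              x$provenance$engine))
  invisible(x)
}

#' Write / read a look-up table as long-form CSV
#'
#' Columns `mus_prime, mua, T, R`; fixed parameters and provenance are kept
#' in `# key: value` header comments.
#'
#' @param lut a `lookup_table`.
#' @param path CSV file path.
#' @return `write_lut` returns `path` invisibly; `read_lut` the table.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "lookup_table"))
  hdr <- sprintf("# %s: %s",
                 c("g", "n_slab", "n_ambient", "d", "engine"),
                 c(lut$fixed$g, lut$fixed$n_slab, lut$fixed$n_ambient,
                   lut$fixed$d, lut$provenance$engine))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines("mus_prime,mua,T,R", con)
  for (j in seq_along(lut$grid_mua))
    for (i in seq_along(lut$grid_mus_prime))
      writeLines(sprintf("%.12g,%.12g,%.12g,%.12g",
                         lut$grid_mus_prime[i], lut$grid_mua[j],
                         lut$table_T[i, j], lut$table_R[i, j]), con)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), ": "))
  meta <- setNames(as.list(kv[, 2]), kv[, 1])
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  mus <- sort(unique(df$mus_prime)); mua <- sort(unique(df$mua))
  nT <- matrix(NA_real_, length(mus), length(mua))
  nR <- nT
  ii <- match(df$mus_prime, mus); jj <- match(df$mua, mua)
  nT[cbind(ii, jj)] <- df$T; nR[cbind(ii, jj)] <- df$R
  structure(list(grid_mus_prime = mus, grid_mua = mua,
                 fixed = list(g = as.numeric(meta$g),
                              n_slab = as.numeric(meta$n_slab),
                              n_ambient = as.numeric(meta$n_ambient),
                              d = as.numeric(meta$d)),
                 table_T = nT, table_R = nR,
                 provenance = list(engine = meta$engine, budget = NA,
                                   seed = NA)),
            class = "lookup_table")
}

# bilinear interpolation of both tables on (mus', log10 mua) with gradient
lut_interp <- function(lut, mus_prime, mua) {
  x <- lut$grid_mus_prime; y <- log10(lut$grid_mua)
  xv <- mus_prime; yv <- log10(mua)
  i <- max(1L, min(length(x) - 1L, findInterval(xv, x)))
  j <- max(1L, min(length(y) - 1L, findInterval(yv, y)))
  dx <- x[i + 1L] - x[i]; dy <- y[j + 1L] - y[j]
  u <- (xv - x[i]) / dx; v <- (yv - y[j]) / dy
  bil <- function(M) {
    f11 <- M[i, j]; f21 <- M[i + 1L, j]
    f12 <- M[i, j + 1L]; f22 <- M[i + 1L, j + 1L]
    val <- f11 * (1 - u) * (1 - v) + f21 * u * (1 - v) +
           f12 * (1 - u) * v + f22 * u * v
    list(val = val,
         dx = ((f21 - f11) * (1 - v) + (f22 - f12) * v) / dx,
         dy = ((f12 - f11) * (1 - u) + (f22 - f21) * u) / dy)
  }
  list(T = bil(lut$table_T), R = bil(lut$table_R), cell = c(i, j))
}

#' Invert sphere observables to optical properties via the look-up table
#'
#' Finds the \eqn{(\mu_s', \mu_a)} whose bilinearly interpolated forward
#' observables (on the \eqn{(\mu_s', \log_{10}\mu_a)} plane) match the
#' measured pair, by damped Newton iteration on the interpolated surfaces
#' initialized at the best grid node.
#'
#' @param T_meas,R_meas measured total hemispherical transmittance and
#'   reflectance, each in (0, 1) with `T_meas + R_meas < 1`.
#' @param lut a `lookup_table` from [build_lut()].
#' @param tol convergence tolerance on the residual norm.
#' @return Named list `mus_prime`, `mua`, and `diagnostics` (residual norm,
#'   bracketing cell, iteration count).
#' @export
lut_invert <- function(T_meas, R_meas, lut, tol = 1e-12) {
  stopifnot(inherits(lut, "lookup_table"))
  if (!is.finite(T_meas) || !is.finite(R_meas) ||
      T_meas <= 0 || R_meas < 0 || T_meas + R_meas >= 1)
    stop("infeasible observable pair: need 0 < T, 0 <= R, T + R < 1")
  rngT <- range(lut$table_T); rngR <- range(lut$table_R)
  pad <- 1e-9
  if (T_meas < rngT[1] - pad || T_meas > rngT[2] + pad)
    stop(sprintf("T = %g outside the table range [%g, %g] (mus'/mua axes too narrow)",
                 T_meas, rngT[1], rngT[2]))
  if (R_meas < rngR[1] - pad || R_meas > rngR[2] + pad)
    stop(sprintf("R = %g outside the table range [%g, %g] (mus'/mua axes too narrow)",
                 R_meas, rngR[1], rngR[2]))

  # grid-scan initialization
  res2 <- (lut$table_T - T_meas)^2 + (lut$table_R - R_meas)^2
  k <- arrayInd(which.min(res2), dim(res2))
  x <- lut$grid_mus_prime[k[1]]
  yl <- log10(lut$grid_mua[k[2]])
  xrng <- range(lut$grid_mus_prime); yrng <- log10(range(lut$grid_mua))

  last_cell <- c(NA, NA); rnorm_ <- Inf; it <- 0L
  for (it in seq_len(200L)) {
    ip <- lut_interp(lut, x, 10^yl)
    fT <- ip$T$val - T_meas; fR <- ip$R$val - R_meas
    rnorm_ <- sqrt(fT^2 + fR^2)
    last_cell <- ip$cell
    if (rnorm_ < tol) break
    J <- matrix(c(ip$T$dx, ip$T$dy, ip$R$dx, ip$R$dy), 2, 2, byrow = TRUE)
    detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (!is.finite(detJ) || abs(detJ) < 1e-300)
      stop("singular interpolation Jacobian: non-unique bracketing (fold-over) ",
           "near mus' = ", signif(x, 6), ", mua = ", signif(10^yl, 6))
    step <- -solve(J, c(fT, fR))
    # damping: limit the step to one cell width
    step[1] <- sign(step[1]) * min(abs(step[1]), diff(xrng) / 8)
    step[2] <- sign(step[2]) * min(abs(step[2]), diff(yrng) / 8)
    x <- min(max(x + step[1], xrng[1]), xrng[2])
    yl <- min(max(yl + step[2], yrng[1]), yrng[2])
  }
  if (rnorm_ > 1e-6) {
    hit_edge <- x <= xrng[1] || x >= xrng[2] || yl <= yrng[1] || yl >= yrng[2]
    ax <- if (x <= xrng[1] || x >= xrng[2]) "mus_prime" else "mua"
    if (hit_edge)
      stop(sprintf("target (T = %g, R = %g) is outside the invertible table range on the %s axis",
                   T_meas, R_meas, ax))
  }
  list(mus_prime = x, mua = 10^yl,
       diagnostics = list(residual = rnorm_, cell = last_cell,
                          iterations = it))
}
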