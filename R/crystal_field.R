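#' Construct a principal g-tensor
#'
#' Holds the three principal values of the effective Zeeman tensor of an
#' S = 1/2 centre, with optional 1-sigma uncertainties. The Griffith-Taylor
#' formalism assumes the proper axis system gz >= gy >= gx; inputs are
#' re-sorted into that canonical order on construction (a warning is issued
#' if reordering was needed), with uncertainties carried along.
#'
#' @param gz,gy,gx Principal g-values (dimensionless, strictly positive).
#' @param sigma Numeric vector of length 3: 1-sigma uncertainties on
#'   (gz, gy, gx). Defaults to zero.
#' @param label Free-text sample identifier.
#' @return An object of class `gtensor`: a list with fields `gz`, `gy`,
#'   `gx`, `sigma_gz`, `sigma_gy`, `sigma_gx`, `label`.
#' @export
#' @examples
#' gtensor(2.44, 2.25, 1.92, sigma = c(0.005, 0.002, 0.002), label = "resting")
gtensor <- function(gz, gy, gx, sigma = c(0, 0, 0), label = "") {
  g <- c(gz, gy, gx)
  if (!is.numeric(g) || length(g) != 3L || any(!is.finite(g))) {
    stop("gz, gy, gx must be three finite numbers", call. = FALSE)
  }
  if (any(g <= 0)) stop("all g-values must be strictly positive", call. = FALSE)
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (any(is.na(sigma)) || any(sigma < 0)) {
    stop("uncertainties must be non-negative (use 0 for 'unknown')", call. = FALSE)
  }
  ord <- order(g, decreasing = TRUE)
  if (!identical(ord, 1:3)) {
    warning("g-values reordered into canonical gz >= gy >= gx", call. = FALSE)
    g <- g[ord]
    sigma <- sigma[ord]
  }
  structure(
    list(gz = g[1], gy = g[2], gx = g[3],
         sigma_gz = sigma[1], sigma_gy = sigma[2], sigma_gx = sigma[3],
         label = as.character(label)),
    class = "gtensor"
  )
}

#' @export
print.gtensor <- function(x, ...) {
  cat(sprintf("g-tensor%s: gz = %.4g +/- %.2g, gy = %.4g +/- %.2g, gx = %.4g +/- %.2g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$gz, x$sigma_gz, x$gy, x$sigma_gy, x$gx, x$sigma_gx))
  invisible(x)
}

.as_gtensor <- function(g) {
  if (inherits(g, "gtensor")) return(g)
  if (is.numeric(g) && length(g) == 3L) return(gtensor(g[1], g[2], g[3]))
  stop("expected a 'gtensor' or a numeric vector of three g-values", call. = FALSE)
}

#' Orbital mixing coefficients from the principal g-values
#'
#' Inverts the one-hole (Griffith-Taylor) model for a low-spin d5 centre:
#' the Kramers ground doublet is an admixture of the three t2g orbitals
#' with coefficients a (d_yz), b (d_xz) and c (d_xy). With
#' D = sqrt(8 (gz + gy - gx)) the coefficients follow as
#' a = (gz + gy)/D, b = (gz - gx)/D, c = (gy - gx)/D, and the normalization
#' m^2 = a^2 + b^2 + c^2 measures the adequacy of the pure-t2g description
#' (m^2 < 1: covalent delocalization; m^2 > 1: excited-state admixture).
#'
#' @param g A [gtensor] or numeric vector `c(gz, gy, gx)`.
#' @return An object of class `orbital_coefficients`: list with `a`, `b`,
#'   `c`, `m_squared`.
#' @seealso [g_from_coefficients()] for the forward map.
#' @export
#' @examples
#' coefficients_from_g(c(2.440, 2.25, 1.92))
coefficients_from_g <- function(g) {
  g <- .as_gtensor(g)
  arg <- g$gz + g$gy - g$gx
  if (arg <= 0) {
    stop("invalid g-tensor: gz + gy - gx must be positive (got ",
         signif(arg, 6), ")", call. = FALSE)
  }
  D <- sqrt(8 * arg)
  a <- (g$gz + g$gy) / D
  b <- (g$gz - g$gx) / D
  cc <- (g$gy - g$gx) / D
  structure(
    list(a = a, b = b, c = cc, m_squared = a^2 + b^2 + cc^2),
    class = "orbital_coefficients"
  )
}

#' @export
print.orbital_coefficients <- function(x, ...) {
  cat(sprintf("orbital coefficients: a = %.4f, b = %.4f, c = %.4f, m^2 = %.4f\n",
              x$a, x$b, x$c, x$m_squared))
  invisible(x)
}

#' Principal g-values from orbital mixing coefficients
#'
#' Forward map of the one-hole model:
#' gz = 2\[(a+b)^2 - c^2\], gy = 2\[(a+c)^2 - b^2\], gx = 2\[a^2 - (b+c)^2\].
#'
#' @param a,b,c Mixing coefficients; alternatively pass an
#'   `orbital_coefficients` object as `a`.
#' @return A [gtensor] with zero uncertainties.
#' @export
#' @examples
#' g_from_coefficients(1, 0, 0)   # pure d_yz hole: isotropic g = 2
g_from_coefficients <- function(a, b = NULL, c = NULL) {
  if (inherits(a, "orbital_coefficients")) {
    b <- a$b; c <- a$c; a <- a$a
  }
  if (a + b + c <= 0) {
    stop("invalid coefficients: a + b + c must be positive", call. = FALSE)
  }
  gz <- 2 * ((a + b)^2 - c^2)
  gy <- 2 * ((a + c)^2 - b^2)
  gx <- 2 * (a^2 - (b + c)^2)
  gtensor(gz, gy, gx)
}

# V/xi and Delta/xi in Taylor's standard form, plus analytic partials
# with respect to (gz, gy, gx). Vectorized over the g arguments (used by
# the Monte-Carlo propagation); partials come back as 3-column matrices.
.cf_core <- function(gz, gy, gx) {
  s <- gz + gy
  dzx <- gz - gx
  dyx <- gy - gx
  v <- gx / s + gy / dzx
  dv <- cbind(gz = -gx / s^2 - gy / dzx^2,
              gy = -gx / s^2 + 1 / dzx,
              gx =  1 / s + gy / dzx^2)
  d <- gx / s + gz / dyx - v / 2
  dd <- cbind(gz = -gx / s^2 + 1 / dyx - dv[, "gz"] / 2,
              gy = -gx / s^2 - gz / dyx^2 - dv[, "gy"] / 2,
              gx =  1 / s + gz / dyx^2 - dv[, "gx"] / 2)
  r <- v / d
  dr <- (dv * d - v * dd) / d^2
  list(v = v, d = d, r = r, dv = dv, dd = dd, dr = dr)
}

.new_cf_params <- function(v, d, r, sv = NA_real_, sd = NA_real_, sr = NA_real_,
                           xi = NULL, label = "") {
  out <- list(v_over_xi = v, delta_over_xi = d, rhombicity = r,
              sigma_v = sv, sigma_delta = sd, sigma_rhombicity = sr,
              v_abs = if (!is.null(xi)) v * xi else NA_real_,
              delta_abs = if (!is.null(xi)) d * xi else NA_real_,
              xi = if (!is.null(xi)) xi else NA_real_,
              label = label)
  class(out) <- "crystal_field_params"
  out
}

#' @export
print.crystal_field_params <- function(x, ...) {
  cat(sprintf("crystal-field parameters%s:\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  V/xi = %.3f   Delta/xi = %.3f   V/Delta = %.3f\n",
              x$v_over_xi, x$delta_over_xi, x$rhombicity))
  if (!is.na(x$sigma_v)) {
    cat(sprintf("  +/-    %.3f          %.3f            %.3f\n",
                x$sigma_v, x$sigma_delta, x$sigma_rhombicity))
  }
  if (!is.na(x$v_abs)) {
    cat(sprintf("  with xi = %g cm^-1: V = %.0f cm^-1, Delta = %.0f cm^-1\n",
                x$xi, x$v_abs, x$delta_abs))
  }
  invisible(x)
}

#' Crystal-field parameters from the principal g-values
#'
#' Computes the rhombic and axial crystal-field splittings of the t2g set
#' in units of the spin-orbit coupling constant xi, in Taylor's standard
#' form:
#' \deqn{V/\xi = g_x/(g_z+g_y) + g_y/(g_z-g_x)}
#' \deqn{\Delta/\xi = g_x/(g_z+g_y) + g_z/(g_y-g_x) - (V/\xi)/2}
#' The rhombicity V/Delta classifies the axial ligand set; Delta tracks the
#' axial ligand-field strength. For free ferric iron xi is about 400 cm^-1,
#' so supplying `xi` converts the ratios to absolute energies.
#'
#' @param g A [gtensor] or numeric `c(gz, gy, gx)`.
#' @param xi Optional spin-orbit coupling constant in cm^-1. When given,
#'   absolute V and Delta (cm^-1) are populated.
#' @return A `crystal_field_params` object with fields `v_over_xi`,
#'   `delta_over_xi`, `rhombicity` (= V/Delta), and `v_abs`/`delta_abs` in
#'   cm^-1 when `xi` was supplied. Uncertainty fields are `NA`; see
#'   [propagate_uncertainties()].
#' @export
#' @examples
#' crystal_field_ratios(c(2.440, 2.25, 1.92))
#' crystal_field_ratios(c(2.440, 2.25, 1.92), xi = 400)
crystal_field_ratios <- function(g, xi = NULL) {
  g <- .as_gtensor(g)
  if (g$gz <= g$gx || g$gy <= g$gx) {
    which_d <- if (g$gz <= g$gx) "gz - gx" else "gy - gx"
    stop("degenerate g-tensor: denominator ", which_d, " vanishes", call. = FALSE)
  }
  core <- .cf_core(g$gz, g$gy, g$gx)
  .new_cf_params(core$v, core$d, core$r, xi = xi, label = g$label)
}

#' Propagate g-value uncertainties onto the crystal-field parameters
#'
#' Three propagation rules are offered for the map
#' (gz, gy, gx) -> (V/xi, Delta/xi, V/Delta):
#' `linear_sum` is the worst-case linear rule sum_i |df/dg_i| sigma_i with
#' analytic partial derivatives; `quadrature` is the root-sum-square of the
#' same terms (never larger than `linear_sum`, by the triangle inequality);
#' `monte_carlo` draws independent Gaussian g-values and reports sample
#' standard deviations.
#'
#' @param g A [gtensor] whose `sigma_*` fields are set (zero is allowed and
#'   yields zero output uncertainties).
#' @param method One of `"linear_sum"` (default), `"quadrature"`,
#'   `"monte_carlo"`.
#' @param n_draws Number of Monte-Carlo draws (>= 1000); ignored otherwise.
#' @param seed Integer RNG seed, required for `"monte_carlo"` so that
#'   results are reproducible.
#' @param xi Optional spin-orbit constant in cm^-1, passed through.
#' @return A `crystal_field_params` object with `sigma_v`, `sigma_delta`,
#'   `sigma_rhombicity` filled in.
#' @export
#' @examples
#' g <- gtensor(2.440, 2.25, 1.92, sigma = c(0.005, 0.002, 0.002))
#' propagate_uncertainties(g)                       # linear worst case
#' propagate_uncertainties(g, method = "quadrature")
propagate_uncertainties <- function(g,
                                    method = c("linear_sum", "quadrature", "monte_carlo"),
                                    n_draws = 10000L, seed = NULL, xi = NULL) {
  method <- match.arg(method)
  g <- .as_gtensor(g)
  sig <- c(g$sigma_gz, g$sigma_gy, g$sigma_gx)
  if (any(is.na(sig))) {
    stop("configuration error: all sigma fields must be set", call. = FALSE)
  }
  base <- crystal_field_ratios(g, xi = xi)
  if (method == "monte_carlo") {
    if (is.null(seed)) {
      stop("monte_carlo propagation requires an explicit seed", call. = FALSE)
    }
    if (n_draws < 1000L) stop("n_draws must be >= 1000", call. = FALSE)
    if (all(sig == 0)) {
      sv <- sd_ <- sr <- 0
    } else {
      set.seed(as.integer(seed))
      gz <- stats::rnorm(n_draws, g$gz, sig[1])
      gy <- stats::rnorm(n_draws, g$gy, sig[2])
      gx <- stats::rnorm(n_draws, g$gx, sig[3])
      ok <- (gz > gx) & (gy > gx) & (gz + gy > 0)
      core <- .cf_core(gz[ok], gy[ok], gx[ok])
      sv <- stats::sd(core$v); sd_ <- stats::sd(core$d); sr <- stats::sd(core$r)
    }
  } else {
    core <- .cf_core(g$gz, g$gy, g$gx)
    comb <- if (method == "linear_sum") {
      function(dd) sum(abs(as.numeric(dd)) * sig)
    } else {
      function(dd) sqrt(sum((as.numeric(dd) * sig)^2))
    }
    sv <- comb(core$dv); sd_ <- comb(core$dd); sr <- comb(core$dr)
  }
  base$sigma_v <- sv
  base$sigma_delta <- sd_
  base$sigma_rhombicity <- sr
  base
}

#' Batch crystal-field analysis of a table of g-tensors
#'
#' Applies [coefficients_from_g()] and [propagate_uncertainties()] to each
#' row, collecting the results into a data frame with a fixed column order
#' suitable for CSV/JSON export. Failures (e.g. degenerate g-values) are
#' reported per row in the `status` column; the batch continues.
#'
#' An advisory `m2_note` column flags rows whose normalization deviates from
#' unity by more than 0.02: below one suggests covalent spin delocalization
#' onto the ligands, above one admixture of excited states.
#'
#' @param rows A list of [gtensor] objects, or a data frame with columns
#'   `label, gz, gy, gx` and optionally `sgz, sgy, sgx`.
#' @param xi Optional spin-orbit constant (cm^-1).
#' @param method Uncertainty rule, see [propagate_uncertainties()].
#' @param n_draws,seed Monte-Carlo controls, see [propagate_uncertainties()].
#' @return A data frame with columns `label, gz, gy, gx, a, b, c, m2, V_xi,
#'   dV_xi, Delta_xi, dDelta_xi, V_Delta, dV_Delta, m2_note, status`; one
#'   row per input, in input order. Values are raw doubles; see
#'   [format_analysis_table()] for display rounding.
#' @export
#' @examples
#' path <- system.file("extdata", "cw_gtensor_table.csv", package = "hemeEPR")
#' analyze_table(read_gtensor_table(path))
analyze_table <- function(rows, xi = NULL,
                          method = c("linear_sum", "quadrature", "monte_carlo"),
                          n_draws = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (is.data.frame(rows)) rows <- .gtensors_from_df(rows)
  if (!is.list(rows) || length(rows) == 0L) {
    stop("need at least one g-tensor row", call. = FALSE)
  }
  one <- function(g) {
    res <- tryCatch({
      g <- .as_gtensor(g)
      co <- coefficients_from_g(g)
      cf <- propagate_uncertainties(g, method = method,
                                    n_draws = n_draws, seed = seed, xi = xi)
      note <- if (abs(co$m_squared - 1) <= 0.02) "" else if (co$m_squared < 1) {
        "m2 < 0.98: possible covalent delocalization"
      } else {
        "m2 > 1.02: possible excited-state admixture"
      }
      data.frame(label = g$label, gz = g$gz, gy = g$gy, gx = g$gx,
                 a = co$a, b = co$b, c = co$c, m2 = co$m_squared,
                 V_xi = cf$v_over_xi, dV_xi = cf$sigma_v,
                 Delta_xi = cf$delta_over_xi, dDelta_xi = cf$sigma_delta,
                 V_Delta = cf$rhombicity, dV_Delta = cf$sigma_rhombicity,
                 m2_note = note, status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      lab <- tryCatch(if (inherits(g, "gtensor")) g$label else "", error = function(...) "")
      data.frame(label = lab, gz = NA_real_, gy = NA_real_, gx = NA_real_,
                 a = NA_real_, b = NA_real_, c = NA_real_, m2 = NA_real_,
                 V_xi = NA_real_, dV_xi = NA_real_,
                 Delta_xi = NA_real_, dDelta_xi = NA_real_,
                 V_Delta = NA_real_, dV_Delta = NA_real_,
                 m2_note = "", status = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  }
  do.call(rbind, lapply(rows, one))
}

#' Round an analysis table the way it is reported
#'
#' Coefficients (`a`, `b`, `c`, `m2`) to 3 decimals, crystal-field ratios
#' and their uncertainties to 2 decimals; g-values untouched. Intended for
#' printed reports and golden files; [analyze_table()] itself keeps full
#' precision.
#'
#' @param df Output of [analyze_table()].
#' @return The same data frame with rounded numeric columns.
#' @export
format_analysis_table <- function(df) {
  for (col in c("a", "b", "c", "m2")) df[[col]] <- round(df[[col]], 3)
  for (col in c("V_xi", "dV_xi", "Delta_xi", "dDelta_xi", "V_Delta", "dV_Delta")) {
    df[[col]] <- round(df[[col]], 2)
  }
  df
}

.gtensors_from_df <- function(df) {
  need <- c("gz", "gy", "gx")
  if (!all(need %in% names(df))) {
    stop("table must have columns gz, gy, gx (plus optional label, sgz, sgy, sgx)",
         call. = FALSE)
  }
  if (is.null(df$label)) df$label <- paste0("row", seq_len(nrow(df)))
  has_sigma <- all(c("sgz", "sgy", "sgx") %in% names(df))
  lapply(seq_len(nrow(df)), function(i) {
    sig <- if (has_sigma) c(df$sgz[i], df$sgy[i], df$sgx[i]) else c(0, 0, 0)
    gtensor(df$gz[i], df$gy[i], df$gx[i], sigma = sig, label = df$label[i])
  })
}

#' Read a g-tensor table from CSV/TSV
#'
#' Expects columns `label, gz, gy, gx` and optionally `sgz, sgy, sgx`
#' (1-sigma uncertainties); extra columns (e.g. strain, linewidth) are
#' ignored. The packaged fixture `cw_gtensor_table.csv` carries the CW
#' simulation parameters of the five P450 samples studied here.
#'
#' @param path File path; the delimiter is sniffed (comma or tab).
#' @return A data frame (not yet converted to [gtensor] objects).
#' @export
read_gtensor_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gz", "gy", "gx")
  if (!all(need %in% names(df))) {
    stop("table must have columns gz, gy, gx", call. = FALSE)
  }
  df
}

#' Write an analysis report
#'
#' @param df Output of [analyze_table()].
#' @param path Destination; format chosen by `format`.
#' @param format `"csv"` or `"json"`.
#' @param rounded Apply the report rounding of [format_analysis_table()]?
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(df, path, format = c("csv", "json"),
                                  rounded = TRUE) {
  format <- match.arg(format)
  if (rounded) df <- format_analysis_table(df)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
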