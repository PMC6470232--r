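#' Fourier base-function set for pairwise phase dynamics
#'
#' The phase velocity of each oscillator is expanded on a constant term
#' plus the Fourier components \eqn{\sin(k_1\varphi_1 + k_2\varphi_2)} and
#' \eqn{\cos(k_1\varphi_1 + k_2\varphi_2)} over the integer lattice
#' \eqn{\max(|k_1|,|k_2|) \le K}, origin excluded, one canonical
#' representative per \eqn{\pm(k_1,k_2)} class (the sign flip only negates
#' a sine / leaves a cosine, so both signs would be collinear). For K = 2
#' this gives 1 + 12 x 2 = 25 members per equation; for K = 1, 9.
#'
#' @param K Expansion order (>= 1; default 2).
#' @return An object of class `base_function_set`: list with `K` and
#'   `members`, a tibble with columns `term`, `type`
#'   (`"const"`/`"sin"`/`"cos"`), `k1`, `k2` in a deterministic order.
#' @export
#' @examples
#' nrow(build_base_functions(2)$members) # 25
build_base_functions <- function(K = 2) {
  if (!is.numeric(K) || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  lat <- expand.grid(k1 = -K:K, k2 = -K:K)
  lat <- lat[!(lat$k1 == 0 & lat$k2 == 0), ]
  canon <- lat[lat$k1 > 0 | (lat$k1 == 0 & lat$k2 > 0), ]
  canon <- canon[order(canon$k1, canon$k2), ]
  mk <- function(type) {
    tibble::tibble(
      term = sprintf("%s(%+d phi1 %+d phi2)", type, canon$k1, canon$k2),
      type = type, k1 = canon$k1, k2 = canon$k2)
  }
  members <- dplyr::bind_rows(
    tibble::tibble(term = "const", type = "const", k1 = 0L, k2 = 0L),
    mk("sin"), mk("cos"))
  structure(list(K = K, members = members), class = "base_function_set")
}

#' Evaluate a base-function set
#'
#' @param base A [build_base_functions()] set.
#' @param phi1,phi2 Phase vectors (rad), equal length.
#' @return Numeric matrix, samples x members.
#' @export
eval_base_functions <- function(base, phi1, phi2) {
  stopifnot(inherits(base, "base_function_set"),
            length(phi1) == length(phi2))
  m <- base$members
  cl <- m[m$type == "sin", ] # one row per canonical class, in member order
  args <- outer(phi1, cl$k1) + outer(phi2, cl$k2)
  out <- cbind(1, sin(args), cos(args))
  colnames(out) <- m$term
  out
}

# Column sums of the member derivatives w.r.t. phi1 or phi2, from the
# column sums of an already-evaluated design matrix: d sin(arg)/d phi_i =
# k_i cos(arg) (the paired cosine member) and vice versa with a sign flip.
.base_deriv_colsums <- function(base, Bcolsums, wrt) {
  m <- base$members
  k <- if (wrt == 1) m$k1 else m$k2
  n_cl <- (nrow(m) - 1L) / 2L
  i_sin <- 1L + seq_len(n_cl)
  i_cos <- 1L + n_cl + seq_len(n_cl)
  out <- numeric(nrow(m))
  out[i_sin] <- k[i_sin] * Bcolsums[i_cos]
  out[i_cos] <- -k[i_cos] * Bcolsums[i_sin]
  out
}

#' Dynamic Bayesian inference of pairwise phase dynamics
#'
#' Fits the coupled phase-oscillator model
#' \deqn{\dot\varphi_i = \sum_k c^{(i)}_k \Phi_k(\varphi_1, \varphi_2) + \xi_i}
#' jointly for both oscillators by recursive Bayesian estimation. Within a
#' window, phase derivatives are forward differences
#' \eqn{\dot\varphi_n = (\varphi_{n+1}-\varphi_n)/h} with base functions
#' evaluated at the midpoints \eqn{(\varphi_{n+1}+\varphi_n)/2}, and the
#' parameter vector \eqn{c}, its concentration (inverse covariance)
#' \eqn{\Xi} and the 2 x 2 noise intensity matrix \eqn{E} are iterated to
#' a fixed point of
#' \deqn{E = (h/N) \sum_n (\dot\varphi_n - c\,\Phi_n)(\dot\varphi_n - c\,\Phi_n)^T}
#' \deqn{\Xi = \Xi_{prior} + h \sum_n \Phi_n E^{-1} \Phi_n^T}
#' \deqn{r = \Xi_{prior} c_{prior} + h \sum_n \Phi_n E^{-1} \dot\varphi_n
#'   - (h/2) \sum_n \partial\Phi_n/\partial\varphi, \qquad c = \Xi^{-1} r.}
#' Across consecutive windows the posterior becomes the next prior with
#' diffusive inflation of the covariance,
#' \eqn{\Xi_{prior}' = (\Xi_{post}^{-1} + \mathrm{diag}(p_w c)^2)^{-1}},
#' which lets the inferred dynamics drift between windows at a rate set by
#' the propagation constant \eqn{p_w}.
#'
#' With a flat prior, a single window and a fixed (small) noise matrix the
#' estimate reduces to ordinary least squares of the phase derivatives on
#' the base design matrix.
#'
#' @param phi1,phi2 Unwrapped phase series (rad), equal length. `phi1` is
#'   oscillator i, `phi2` oscillator j.
#' @param sampling_rate Hz of the phase series.
#' @param base A [build_base_functions()] set (default K = 2).
#' @param window_s Window length in seconds, or `NULL` (default) for a
#'   single window spanning the record.
#' @param propagation_const Prior diffusion constant `p_w` (default 0.2).
#' @param tol Relative convergence tolerance on the coefficients.
#' @param max_iter Maximum fixed-point iterations per window.
#' @param noise_cov Optional fixed noise matrix E (2 x 2 or scalar for
#'   `E = e I`); when given, E is not re-estimated.
#' @return An object of class `coupling_model`: list with `coefficients`
#'   (members x 2 x windows array; column 1 = equation of `phi1`),
#'   `noise` (2 x 2 x windows), `windows` (tibble: `window`, `start_s`,
#'   `converged`, `iterations`), `base`, `h` and settings.
#' @export
infer_phase_dynamics <- function(phi1, phi2, sampling_rate,
                                 base = build_base_functions(2),
                                 window_s = NULL, propagation_const = 0.2,
                                 tol = 1e-5, max_iter = 100,
                                 noise_cov = NULL) {
  stopifnot(length(phi1) == length(phi2), length(phi1) >= 3)
  h <- 1 / sampling_rate
  n <- length(phi1)
  M <- nrow(base$members)
  win_len <- if (is.null(window_s)) n else max(2L, round(window_s * sampling_rate))
  n_win <- max(1L, floor((n - 1) / max(1L, win_len - 1L)))
  if (is.null(window_s)) n_win <- 1L
  if ((n - 1) / n_win < 10 * M) {
    stop("window holds fewer than 10 x ", M,
         " samples; use longer windows or a smaller base set")
  }
  fixedE <- NULL
  if (!is.null(noise_cov)) {
    fixedE <- if (length(noise_cov) == 1) diag(2) * noise_cov else
      as.matrix(noise_cov)
    stopifnot(identical(dim(fixedE), c(2L, 2L)))
  }

  coefs <- array(NA_real_, c(M, 2, n_win),
                 dimnames = list(base$members$term, c("eq1", "eq2"), NULL))
  noise <- array(NA_real_, c(2, 2, n_win))
  win_conv <- logical(n_win); win_iter <- integer(n_win)
  win_start <- numeric(n_win)
  theta_prior <- numeric(2 * M)
  xi_prior <- matrix(0, 2 * M, 2 * M)
  bounds <- round(seq(1L, n, length.out = n_win + 1L))

  for (w in seq_len(n_win)) {
    idx <- bounds[w]:bounds[w + 1L]
    p1 <- phi1[idx]; p2 <- phi2[idx]
    nw <- length(p1) - 1L
    ydot <- cbind(diff(p1), diff(p2)) / h
    m1 <- (p1[-1] + p1[-length(p1)]) / 2
    m2 <- (p2[-1] + p2[-length(p2)]) / 2
    B <- eval_base_functions(base, m1, m2)
    MBB <- crossprod(B)
    ch <- tryCatch(chol(MBB), error = function(e) NULL)
    if (is.null(ch) || rcond(ch) < 1e-14) {
      ev <- eigen(MBB, symmetric = TRUE)
      v <- abs(ev$vectors[, which.min(ev$values)])
      bad <- base$members$term[order(-v)[1:2]]
      stop("singular design: degenerate base members ",
           paste(bad, collapse = ", "))
    }
    cs <- colSums(B)
    dmat <- cbind(.base_deriv_colsums(base, cs, 1),
                  .base_deriv_colsums(base, cs, 2)) # M x 2
    drift <- (h / 2) * as.vector(dmat)
    BtY <- crossprod(B, ydot)
    flat_prior <- w == 1L || all(xi_prior == 0)
    theta <- as.vector(backsolve(ch, forwardsolve(t(ch), BtY))) # OLS start
    converged <- FALSE; it <- 0L
    E <- fixedE
    repeat {
      it <- it + 1L
      C <- matrix(theta, M, 2)
      if (is.null(fixedE)) {
        R <- ydot - B %*% C
        E <- (h / nw) * crossprod(R)
        E <- E + diag(2) * (1e-12 * max(diag(E), 1e-12))
      }
      Einv <- solve(E)
      if (flat_prior) {
        # With a flat prior the normal equations factor over the kron
        # structure: MBB %*% C %*% Einv = BtY %*% Einv - dmat/2
        rhs <- BtY - (dmat / 2) %*% E
        theta_new <- as.vector(backsolve(ch, forwardsolve(t(ch), rhs)))
      } else {
        xi <- xi_prior + h * kronecker(Einv, MBB)
        r <- as.vector(xi_prior %*% theta_prior) +
          h * as.vector(BtY %*% Einv) - drift
        theta_new <- solve(xi, r)
      }
      delta <- max(abs(theta_new - theta)) / max(max(abs(theta_new)), 1e-12)
      theta <- theta_new
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    if (!converged) {
      warning("window ", w, " did not converge after ", max_iter,
              " iterations")
    }
    coefs[, , w] <- matrix(theta, M, 2)
    noise[, , w] <- E
    win_conv[w] <- converged; win_iter[w] <- it
    win_start[w] <- (bounds[w] - 1L) * h
    if (w < n_win) {
      # posterior -> next prior with diffusion inflation
      xi_post <- xi_prior + h * kronecker(solve(E), MBB)
      sigma_post <- solve(xi_post)
      sigma_next <- sigma_post + diag((propagation_const * theta)^2)
      xi_prior <- solve(sigma_next)
      theta_prior <- theta
    }
  }
  windows <- tibble::new_tibble(
    list(window = seq_len(n_win), start_s = win_start,
         converged = win_conv, iterations = win_iter), nrow = n_win)
  structure(list(coefficients = coefs, noise = noise,
                 windows = windows, base = base, h = h,
                 propagation_const = propagation_const, tol = tol,
                 n_samples = n),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat("<coupling_model> K=", x$base$K, ", ", dim(x$coefficients)[3],
      " window(s), ", dim(x$coefficients)[1], " members/equation\n",
      sep = "")
  invisible(x)
}

#' Directed coupling strength
#'
#' The Euclidean norm, within the target's phase-dynamics equation, of the
#' coefficients of all base members that depend on the source oscillator's
#' phase (source wavenumber non-zero, mixed terms included); one value per
#' window, averaged across windows.
#'
#' @param model A [infer_phase_dynamics()] fit.
#' @param source,target `"phi1"` or `"phi2"` (distinct): `source` is the
#'   influencing oscillator, `target` the influenced one.
#' @return Non-negative scalar \eqn{\sigma_{source \to target}}.
#' @export
#' @examples
#' # sigma of phi2 driving phi1:
#' # coupling_strength(model, source = "phi2", target = "phi1")
coupling_strength <- function(model, source = "phi2", target = "phi1") {
  stopifnot(inherits(model, "coupling_model"),
            source %in% c("phi1", "phi2"), target %in% c("phi1", "phi2"),
            source != target)
  m <- model$base$members
  dep <- if (source == "phi1") m$k1 != 0 else m$k2 != 0
  eq <- if (target == "phi1") 1L else 2L
  per_win <- apply(model$coefficients[dep, eq, , drop = FALSE], 3,
                   function(v) sqrt(sum(v^2)))
  mean(per_win)
}

#' Coupling strengths and direction for both directions of a pair
#'
#' @param model A [infer_phase_dynamics()] fit.
#' @return Tibble with one row per direction (`phi2 -> phi1` and
#'   `phi1 -> phi2`) and the shared direction index.
#' @export
coupling_strengths <- function(model) {
  s21 <- coupling_strength(model, "phi2", "phi1")
  s12 <- coupling_strength(model, "phi1", "phi2")
  tibble::tibble(source = c("phi2", "phi1"), target = c("phi1", "phi2"),
                 sigma = c(s21, s12),
                 direction_index = direction_index(s21, s12) * c(1, -1))
}

#' Direction index of a coupled pair
#'
#' \eqn{D = (\sigma_{j\to i} - \sigma_{i\to j}) /
#'          (\sigma_{j\to i} + \sigma_{i\to j}) \in [-1, 1]}; positive
#' when the j-to-i influence dominates. Undefined (NA, with a warning)
#' when both strengths are zero.
#'
#' @param sigma_j_to_i,sigma_i_to_j Non-negative coupling strengths.
#' @return Scalar in \[-1, 1\], or NA.
#' @export
direction_index <- function(sigma_j_to_i, sigma_i_to_j) {
  stopifnot(sigma_j_to_i >= 0, sigma_i_to_j >= 0)
  tot <- sigma_j_to_i + sigma_i_to_j
  if (tot == 0) {
    warning("both coupling strengths are zero; direction undefined")
    return(NA_real_)
  }
  (sigma_j_to_i - sigma_i_to_j) / tot
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a coupling model
#'
#' @param x A `coupling_model`.
#' @param ... Unused.
#' @return Tibble with one row per window, equation and base member:
#'   `window`, `equation` (`"phi1"`/`"phi2"`, the oscillator whose phase
#'   velocity the row models), `term`, `type`, `k1`, `k2`, `estimate`
#'   (rad/s).
#' @method tidy coupling_model
#' @export
tidy.coupling_model <- function(x, ...) {
  m <- x$base$members
  n_win <- dim(x$coefficients)[3]
  purrr::map_dfr(seq_len(n_win), function(w) {
    purrr::map_dfr(1:2, function(eqi) {
      tibble::tibble(window = w, equation = c("phi1", "phi2")[eqi],
                     term = m$term, type = m$type, k1 = m$k1, k2 = m$k2,
                     estimate = x$coefficients[, eqi, w])
    })
  })
}

#' Glance at a coupling model
#'
#' @param x A `coupling_model`.
#' @param ... Unused.
#' @return One-row tibble: expansion order, member count, window count,
#'   convergence, step and mean noise intensities.
#' @method glance coupling_model
#' @export
glance.coupling_model <- function(x, ...) {
  tibble::tibble(
    K = x$base$K,
    n_members = nrow(x$base$members),
    n_windows = dim(x$coefficients)[3],
    converged = all(x$windows$converged),
    h = x$h,
    noise_11 = mean(x$noise[1, 1, ]),
    noise_22 = mean(x$noise[2, 2, ])
  )
}
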