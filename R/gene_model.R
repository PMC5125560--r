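#' Default rate constants of the single-gene model
#'
#' The transcription/translation network has one transcription factor (TF),
#' one promoter and global mRNA/protein counters:
#' \itemize{
#'   \item TF + promoter_repressed <-> promoter_active (k_on, k_off)
#'   \item promoter_active -> promoter_active + M (s_A)
#'   \item promoter_repressed -> promoter_repressed + M (s_R, basal)
#'   \item M -> M + P (s_P); M -> 0 (delta_M); P -> 0 (delta_P)
#' }
#' All times are in minutes.  `k_on` is the whole-domain (well-mixed)
#' activation rate; see [reaction_propensities()] for its mesoscopic
#' scaling on the lattice.
#'
#' @return An object of class `rate_constants`: named list with `k_on`,
#'   `k_off` (min^-1), `s_A`, `s_R` (mRNA min^-1), `s_P` (protein min^-1
#'   per mRNA), `delta_M`, `delta_P` (min^-1) and `D_TF` (um^2 min^-1).
#' @examples
#' default_parameters()$s_A  # 50
#' @export
default_parameters <- function() {
  structure(list(
    k_on = 0.1, k_off = 0.1,
    s_A = 50, s_R = 5,
    s_P = 0.2,
    delta_M = 0.1, delta_P = 0.05,
    D_TF = 10
  ), class = "rate_constants")
}

#' Assemble a rate-constant set, overriding defaults
#' @param ... named overrides of any [default_parameters()] field.
#' @return A `rate_constants` object.
#' @export
rate_constants <- function(...) {
  p <- default_parameters()
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad))
    stop("unknown rate constant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(ov)) p[[nm]] <- ov[[nm]]
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rate constants must be finite and non-negative", call. = FALSE)
  structure(p, class = "rate_constants")
}

#' Cell state of the single-gene model
#'
#' @param tf_voxel lattice index of the free TF, or `NA` when bound.
#' @param promoter `"active"` or `"repressed"`; active iff the TF is bound.
#' @param M,P mRNA and protein copy numbers.
#' @param gene_voxel lattice index of the gene locus.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(tf_voxel, promoter = c("repressed", "active"),
                       M = 0L, P = 0L, gene_voxel = 1L) {
  promoter <- match.arg(promoter)
  bound <- promoter == "active"
  if (bound && !is.na(tf_voxel))
    stop("a bound TF has no free lattice position (use tf_voxel = NA)",
         call. = FALSE)
  if (!bound && (is.na(tf_voxel) || tf_voxel < 1L))
    stop("a free TF needs a valid lattice position", call. = FALSE)
  if (M < 0 || P < 0)
    stop("copy numbers must be non-negative", call. = FALSE)
  structure(list(tf_voxel = tf_voxel, promoter = promoter,
                 M = as.integer(M), P = as.integer(P),
                 gene_voxel = as.integer(gene_voxel)),
            class = "cell_state")
}

#' Reaction propensities of the single-gene network
#'
#' TF-promoter binding is localised: it can fire only while the free TF
#' occupies the gene voxel.  With the default domain-scaled convention the
#' binding propensity is then `k_on * N`, so that in the fast-diffusion
#' uncrowded limit (gene-voxel occupancy 1/N) the effective activation
#' rate recovers the well-mixed `k_on`.  With `kon_domain_scaled = FALSE`
#' the propensity is `k_on` per voxel instead.
#'
#' @param state a `cell_state`.
#' @param rates a `rate_constants`.
#' @param N total voxel count of the lattice.
#' @param kon_domain_scaled logical; see above.
#' @return Named numeric vector (min^-1): `bind`, `unbind`, `transcribe`,
#'   `m_decay`, `translate`, `p_decay`.
#' @export
reaction_propensities <- function(state, rates, N,
                                  kon_domain_scaled = TRUE) {
  if (state$M < 0 || state$P < 0)
    stop("invariant violation: negative copy number", call. = FALSE)
  bound <- state$promoter == "active"
  kon_eff <- if (kon_domain_scaled) rates$k_on * N else rates$k_on
  c(
    bind = if (!bound && !is.na(state$tf_voxel) &&
               state$tf_voxel == state$gene_voxel) kon_eff else 0,
    unbind = if (bound) rates$k_off else 0,
    transcribe = if (bound) rates$s_A else rates$s_R,
    m_decay = rates$delta_M * state$M,
    translate = rates$s_P * state$M,
    p_decay = rates$delta_P * state$P
  )
}

#' Deterministic steady state of the transcription/translation subsystem
#'
#' With the promoter clamped, the rate equations give
#' `M_ss = s / delta_M` (s = `s_A` active, `s_R` repressed) and
#' `P_ss = (s_P / delta_P) * M_ss`.
#'
#' @param rates a `rate_constants`.
#' @param promoter `"active"` or `"repressed"`.
#' @return Named numeric vector `c(M_ss, P_ss)`.
#' @examples
#' deterministic_steady_state(default_parameters(), "active")  # M_ss = 500
#' @export
deterministic_steady_state <- function(rates,
                                       promoter = c("active", "repressed")) {
  promoter <- match.arg(promoter)
  if (rates$delta_M <= 0 || rates$delta_P <= 0)
    stop("decay rates must be positive for a steady state", call. = FALSE)
  s <- if (promoter == "active") rates$s_A else rates$s_R
  M <- s / rates$delta_M
  c(M_ss = M, P_ss = rates$s_P / rates$delta_P * M)
}

#' Exact SSA of the effective two-state well-mixed gene model
#'
#' Direct-method stochastic simulation of promoter switching with
#' effective rates `k_plus` (activation) and `k_minus` (deactivation)
#' coupled to transcription, translation and decay, without space.  This
#' is the reduction the spatial model is compared against: its effective
#' rates are measured from spatial switch statistics.
#'
#' @param rates named list with `k_plus`, `k_minus`, `s_A`, `s_R`,
#'   `delta_M` and optionally `s_P`, `delta_P` (default 0: no protein).
#' @param t_end simulated time, min.
#' @param sample_dt sampling interval for the recorded series, min.
#' @param seed integer seed (engine-internal RNG stream).
#' @param initial_active logical initial promoter state.
#' @param M0,P0 initial copy numbers.
#' @return A `crowdsim_trajectory` (see [simulate_cell()]); `tf_voxel` is
#'   `NA` throughout (no space).
#' @export
wellmixed_ssa <- function(rates, t_end, sample_dt = 1, seed = 1L,
                          initial_active = FALSE, M0 = 0L, P0 = 0L) {
  stopifnot(t_end > 0, sample_dt > 0)
  r <- rates
  s_P <- if (is.null(r$s_P)) 0 else r$s_P
  delta_P <- if (is.null(r$delta_P)) 0 else r$delta_P
  out <- cpp_ssa_wellmixed(r$k_plus, r$k_minus, r$s_A, r$s_R, s_P,
                           r$delta_M, delta_P, initial_active,
                           as.integer(M0), as.integer(P0),
                           t_end, sample_dt, as.numeric(seed))
  new_trajectory(out, t_end = t_end, sample_dt = sample_dt, seed = seed,
                 initial_active = initial_active, spatial = FALSE)
}
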