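#' Inversion-prepared Look-Locker signal train
#'
#' Simulates the signed signal sampled at each excitation of the
#' inversion-prepared small-flip-angle train. Longitudinal magnetization is
#' inverted to `(1 - 2 * efficiency) * M0` (so efficiency 1 is an ideal
#' inversion and efficiency 0 leaves the magnetization untouched), then
#' per readout recovers for one
#' `readout_spacing` (`first_delay` before the first), is sampled through
#' `sin(alpha)`, and is reduced by `cos(alpha)` by the excitation:
#'
#' \deqn{M_z \leftarrow M_0 + (M_z - M_0) e^{-\tau/T_1}; \quad
#'       s_i = \sin\alpha \, M_z; \quad M_z \leftarrow \cos\alpha \, M_z}
#'
#' T2 decay over the (very short) echo time is neglected. With
#' `n_dummy_shots > 0` the train is re-run that many times, carrying the
#' end-of-train magnetization through the remaining TR recovery into the
#' next inversion, to simulate the approach to an inter-shot steady state;
#' the default starts each shot from equilibrium.
#'
#' @param tissue A [tissue_params()] object (only `t1` and `m0` are used).
#' @param protocol A [samba_t1_protocol()].
#' @param n_dummy_shots Number of un-sampled preparatory shots.
#' @return Numeric vector of length `protocol$n_readouts` of signed signal
#'   values (arbitrary units, proportional to `m0`).
#' @examples
#' s <- ll_ir_signal(tissue_params(1000, 80), samba_t1_protocol())
#' @export
ll_ir_signal <- function(tissue, protocol, n_dummy_shots = 0L) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "samba_t1_protocol"))
  t1 <- tissue$t1
  if (!is.finite(t1) || t1 <= 0)
    stop("T1 must be finite and positive", call. = FALSE)
  m0 <- tissue$m0
  n <- protocol$n_readouts
  tau <- protocol$readout_spacing
  alpha <- protocol$excitation_flip_deg * pi / 180
  eff <- protocol$inversion_efficiency
  e_tau <- exp(-tau / t1)
  e_first <- exp(-protocol$first_delay / t1)
  ca <- cos(alpha); sa <- sin(alpha)

  run_shot <- function(mz_pre) {
    # mz_pre: longitudinal magnetization just before the inversion pulse;
    # an inversion of efficiency e maps Mz to (1 - 2e) Mz, matching the
    # (1 - 2 e exp(-TI/T1)) convention of the IR spin-echo model
    mz <- (1 - 2 * eff) * mz_pre
    s <- numeric(n)
    for (i in seq_len(n)) {
      e <- if (i == 1L) e_first else e_tau
      mz <- m0 + (mz - m0) * e
      s[i] <- sa * mz
      mz <- ca * mz
    }
    list(signal = s, mz_end = mz)
  }

  mz_pre <- m0
  if (n_dummy_shots > 0L) {
    t_train <- protocol$first_delay + (n - 1L) * tau
    t_rest <- max(protocol$tr - t_train, 0)
    e_rest <- exp(-t_rest / t1)
    for (d in seq_len(n_dummy_shots)) {
      shot <- run_shot(mz_pre)
      mz_pre <- m0 + (shot$mz_end - m0) * e_rest
    }
  }
  run_shot(mz_pre)$signal
}

#' Train sampling times of a Look-Locker protocol
#'
#' Times of each readout relative to the inversion pulse, ms:
#' `first_delay + (i - 1) * readout_spacing`.
#'
#' @param protocol A [samba_t1_protocol()].
#' @return Numeric vector of length `n_readouts`.
#' @export
ll_train_times <- function(protocol) {
  stopifnot(inherits(protocol, "samba_t1_protocol"))
  protocol$first_delay +
    (seq_len(protocol$n_readouts) - 1L) * protocol$readout_spacing
}

#' T2-preparation decay signal
#'
#' Mono-exponential transverse decay under an ideal T2 preparation:
#' \eqn{s_j = M_0 e^{-TP_j / T_2}}. Relaxation during the preparation
#' block itself is not modeled.
#'
#' @param tissue A [tissue_params()] object (only `t2` and `m0` are used).
#' @param prep_times Vector of preparation times, ms (all >= 0).
#' @return Numeric vector of signals, one per preparation time.
#' @examples
#' t2prep_signal(tissue_params(1000, 100), c(0, 50, 100))
#' @export
t2prep_signal <- function(tissue, prep_times) {
  stopifnot(inherits(tissue, "tissue_params"))
  if (!is.finite(tissue$t2) || tissue$t2 <= 0)
    stop("T2 must be finite and positive", call. = FALSE)
  if (any(prep_times < 0)) stop("prep_times must be >= 0", call. = FALSE)
  tissue$m0 * exp(-prep_times / tissue$t2)
}

#' Inversion-recovery spin-echo signal
#'
#' Signed IR signal with the finite-TR recovery term:
#' \eqn{s_k = M_0 (1 - 2\epsilon e^{-TI_k/T_1} + e^{-TR/T_1})}.
#' Disabling `include_tr_recovery` drops the \eqn{e^{-TR/T_1}} term
#' (the TR-to-infinity idealization).
#'
#' @param tissue A [tissue_params()] object.
#' @param protocol A [se_ir_protocol()].
#' @param include_tr_recovery Include the finite-TR term (default `TRUE`).
#' @return Signed signal vector, one value per inversion time.
#' @export
ir_se_signal <- function(tissue, protocol, include_tr_recovery = TRUE) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "se_ir_protocol"))
  t1 <- tissue$t1
  if (!is.finite(t1) || t1 <= 0)
    stop("T1 must be finite and positive", call. = FALSE)
  ti <- protocol$inversion_times
  eff <- protocol$inversion_efficiency
  rec <- if (include_tr_recovery) exp(-protocol$tr / t1) else 0
  tissue$m0 * (1 - 2 * eff * exp(-ti / t1) + rec)
}

#' T2-prepared spin-echo signal
#'
#' Same mono-exponential decay model as [t2prep_signal()], evaluated at the
#' protocol's preparation times.
#'
#' @param tissue A [tissue_params()] object.
#' @param protocol A [se_t2_protocol()].
#' @return Signal vector, one value per preparation time.
#' @export
se_t2_signal <- function(tissue, protocol) {
  stopifnot(inherits(protocol, "se_t2_protocol"))
  t2prep_signal(tissue, protocol$prep_times)
}

#' Evaluate a protocol's signal model
#'
#' Dispatches to the signal model matching the protocol type; used by the
#' dictionary builder and the phantom simulator so that every consumer runs
#' the identical physics.
#'
#' @param tissue A [tissue_params()] object.
#' @param protocol Any protocol object.
#' @param ... Passed to the underlying model.
#' @return Signed signal vector (one value per frame of the protocol).
#' @export
protocol_signal <- function(tissue, protocol, ...) {
  switch(protocol_type(protocol),
         samba_t1_protocol = ll_ir_signal(tissue, protocol, ...),
         samba_t2_protocol = t2prep_signal(tissue, protocol$prep_times),
         se_ir_protocol = ir_se_signal(tissue, protocol, ...),
         se_t2_protocol = se_t2_signal(tissue, protocol),
         stop("unknown protocol type", call. = FALSE))
}

#' Frame-axis values of a protocol
#'
#' The acquisition-axis value attached to each frame: train times for the
#' Look-Locker protocol, preparation times for T2 protocols, inversion
#' times for the IR spin-echo protocol.
#'
#' @param protocol Any protocol object.
#' @return Numeric vector, ms, one value per frame.
#' @export
protocol_frame_axis <- function(protocol) {
  switch(protocol_type(protocol),
         samba_t1_protocol = ll_train_times(protocol),
         samba_t2_protocol = protocol$prep_times,
         se_ir_protocol = protocol$inversion_times,
         se_t2_protocol = protocol$prep_times,
         stop("unknown protocol type", call. = FALSE))
}
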