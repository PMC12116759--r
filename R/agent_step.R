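# Reference (autodiff) implementation of one CQL+IQN gradient step.
#
# Mirrors src/dcql_step.cpp: all random quantities except dropout masks are
# passed in, so at dropout_p = 0 the two engines produce identical gradients
# (asserted in the test suite). The compiled engine is the default for
# speed; this one is the independently checkable definition.

dcql_step_r <- function(critic, target, actor, s, a, r, cont, s2, a2,
                        a_ood, taus_t, taus_o, taus_d, taus_m, taus_a,
                        eps, cfg) {
  B <- nrow(s)
  K <- length(taus_o) %/% B
  Kt <- length(taus_t) %/% B
  Kc <- length(taus_d) %/% B
  Ka <- length(taus_a) %/% B
  M <- ncol(a_ood)

  zt <- critic_infer(target, s2, a2, taus_t, Kt, cfg)
  y <- r + cfg$discount * cont * zt   # B x Kt, recycled by column

  wp <- wrap_params(critic)
  tau_mat <- matrix(taus_o, B, K, byrow = TRUE)
  z <- critic_graph(wp, s, a, taus_o, B, K, cfg, train = TRUE)
  j_cols <- rep(seq_len(Kt), each = K)
  i_cols <- rep(seq_len(K), times = Kt)
  u <- ad_addc(ad_scale(ad_cols(z, i_cols), -1), y[, j_cols, drop = FALSE])
  wq <- abs(tau_mat[, i_cols, drop = FALSE] - (u$value < 0))
  td_loss <- ad_scale(ad_mean(ad_mulc(ad_huber(u, cfg$huber_kappa),
                                      wq / cfg$huber_kappa)), K)

  q_data <- ad_row_means(critic_graph(wp, s, a, taus_d, B, Kc, cfg,
                                      train = TRUE))
  s_rep <- s[rep(seq_len(B), each = M), , drop = FALSE]
  q_ood <- ad_row_means(critic_graph(wp, s_rep, as.vector(t(a_ood)),
                                     taus_m, B * M, Kc, cfg, train = TRUE))
  lse <- ad_logsumexp_rows(ad_col_to_mat(q_ood, B, M))
  cql_loss <- ad_mean(ad_sub(lse, q_data))
  critic_loss <- ad_add(td_loss, ad_scale(cql_loss, cfg$cql_alpha))
  ad_backward(critic_loss)
  critic_grads <- grads_of(wp)

  wa <- wrap_params(actor)
  out <- mlp_forward(s, wa, dropout_p = cfg$dropout_p, train = TRUE)
  mu <- ad_cols(out, 1L)
  log_std <- ad_addc(ad_scale(ad_tanh(ad_cols(out, 2L)), 2), -1)
  zn <- ad_add(mu, ad_mul(ad_exp(log_std), ad_const(matrix(eps, ncol = 1L))))
  tz <- ad_tanh(zn)
  act <- ad_addc(ad_scale(tz, cfg$action_max / 2), cfg$action_max / 2)
  log_jac <- ad_log(ad_addc(
    ad_scale(ad_square(tz), -cfg$action_max / 2), cfg$action_max / 2 + 1e-6))
  log_prob <- ad_sub(ad_addc(ad_scale(log_std, -1),
                             -0.5 * eps^2 - 0.5 * log(2 * pi)), log_jac)
  wc_const <- wrap_params(critic)   # gradients discarded
  q_pi <- ad_row_means(critic_graph(wc_const, s, act, taus_a, B, Ka, cfg))
  actor_loss <- ad_mean(ad_sub(ad_scale(log_prob, cfg$entropy_coeff), q_pi))
  ad_backward(actor_loss)

  list(critic_grads = critic_grads, actor_grads = grads_of(wa),
       td_loss = td_loss$value[1], cql_loss = cql_loss$value[1],
       critic_loss = critic_loss$value[1], actor_loss = actor_loss$value[1])
}

# Dispatch one gradient step after drawing the step's random quantities.
dcql_step <- function(critic, target, actor, dataset, idx, cfg, engine) {
  B <- length(idx)
  s <- dataset$states[idx, , drop = FALSE]
  a <- dataset$actions[idx]
  r <- dataset$rewards[idx]
  s2 <- dataset$next_states[idx, , drop = FALSE]
  cont <- as.numeric(!dataset$done[idx])
  K <- cfg$n_quantile_samples
  Kc <- cfg$n_cql_quantile_samples
  M1 <- cfg$n_ood_action_samples
  M2 <- cfg$n_actor_action_samples

  a2 <- actor_sample_infer(actor, s2, cfg)
  taus_t <- stats::runif(B * K)
  taus_o <- stats::runif(B * K)
  taus_d <- stats::runif(B * Kc)
  a_unif <- matrix(stats::runif(B * M1, 0, cfg$action_max), B, M1)
  a_pi <- if (M2 > 0) {
    matrix(actor_sample_infer(actor, s[rep(seq_len(B), M2), , drop = FALSE],
                              cfg), B, M2)
  } else NULL
  a_ood <- cbind(a_unif, a_pi)
  taus_m <- stats::runif(B * ncol(a_ood) * Kc)
  taus_a <- stats::runif(B * Kc)
  eps <- stats::rnorm(B)

  if (engine == "cpp") {
    .dcql_step_cpp(critic, target, actor, s, a, r, cont, s2, a2, a_ood,
                   taus_t, taus_o, taus_d, taus_m, taus_a, eps,
                   cfg$dropout_p, cfg$action_max, cfg$discount,
                   cfg$cql_alpha, cfg$huber_kappa, cfg$entropy_coeff,
                   cfg$quantile_embed_dim)
  } else {
    dcql_step_r(critic, target, actor, s, a, r, cont, s2, a2, a_ood,
                taus_t, taus_o, taus_d, taus_m, taus_a, eps, cfg)
  }
}
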