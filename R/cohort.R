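#' Draw a cohort of animal models
#'
#' Each animal gets its own multiplicative amplitude and rate factors, a
#' shared latency shift, mirrored per-nerve-type hotspot jitter, a spatial
#' attenuation length, and a lateral/rostro-caudal electrode-array shift,
#' all drawn around the cohort means in `config$physiology`. Nerve-type
#' offsets are scaled by `effect_scale` and every left/right difference by
#' `asymmetry_scale`, so `effect_scale = 0` yields four statistically
#' identical nerves and `asymmetry_scale = 0` yields mirror-symmetric
#' bilateral pairs.
#'
#' @param config A [generator_config()].
#' @return A list of `dcn_animal` objects, one per animal.
#' @export
make_cohort <- function(config = generator_config()) {
  validate_config(config)
  with_seed(derive_seed(config$rng_seed, 101L), {
    lapply(seq_len(config$n_animals), function(i) draw_animal(i, config))
  })
}

## One animal: called inside make_cohort's RNG stream.
draw_animal <- function(i, config) {
  p <- config$physiology
  av <- config$animal_variability_sd
  es <- config$effect_scale
  as_ <- config$asymmetry_scale

  amp_factor <- max(0.4, 1 + stats::rnorm(1, 0, av))
  rate_factor <- max(0.4, 1 + stats::rnorm(1, 0, av))
  latency_shift <- stats::rnorm(1, 0, 10 * av)      # ms, shared by all nerves
  att <- max(0.3, p$attenuation_length * (1 + stats::rnorm(1, 0, av)))
  shift <- stats::rnorm(2, 0, config$electrode_shift_sd)  # um (lateral, rc)

  ## Hotspot jitter drawn once per nerve type and mirrored across sides so
  ## that asymmetry_scale = 0 keeps bilateral pairs mirror-symmetric.
  jit <- list(sural = stats::rnorm(2, 0, 5 * av * 0.1),
              peroneal = stats::rnorm(2, 0, 5 * av * 0.1))

  nerves <- lapply(NERVES, function(nv) {
    side <- nerve_side(nv)
    type <- nerve_type(nv)
    t_sign <- if (type == "sural") 1 else -1       # latency: sural later
    r_sign <- if (type == "peroneal") 1 else -1    # rate: peroneal higher
    s_sign <- if (side == "R") 1 else -1
    right <- side == "R"

    gain_side <- 1 + es * as_ * p$right_gain * right
    n1_lat <- p$n1_latency + es * t_sign * p$n1_latency_type +
      latency_shift - es * as_ * p$n1_latency_side * right
    p1_lat <- p$p1_latency + latency_shift
    if (p1_lat <= 5) {
      adj <- 5.01 - p1_lat
      p1_lat <- p1_lat + adj
      n1_lat <- n1_lat + adj
    }
    if (n1_lat <= p1_lat + 1) n1_lat <- p1_lat + 1

    hx <- s_sign * es * (p$hotspot_lateral + jit[[type]][1]) -
      right * es * as_ * p$hotspot_asym
    hy <- es * (t_sign * -p$hotspot_rc + jit[[type]][2])

    list(
      p1_latency = p1_lat,
      p1_amplitude = p$p1_amplitude * amp_factor * gain_side,
      n1_latency = n1_lat,
      n1_amplitude = (p$n1_amplitude + es * t_sign * p$n1_amplitude_type) *
        amp_factor * gain_side,
      hf_rate = max(0, (p$hf_rate + es * r_sign * p$hf_rate_type) * rate_factor),
      hf_amplitude = p$hf_event_amplitude * amp_factor * gain_side,
      hotspot = c(x = hx, y = hy)
    )
  })
  names(nerves) <- NERVES

  structure(
    list(animal_id = sprintf("A%d", i),
         nerves = nerves,
         attenuation_length = att,
         electrode_shift = c(lateral = shift[1], rostrocaudal = shift[2])),
    class = "dcn_animal"
  )
}

#' @export
print.dcn_animal <- function(x, ...) {
  cat(sprintf("<dcn_animal %s>  attenuation %.2f mm, shift (%.0f, %.0f) um\n",
              x$animal_id, x$attenuation_length,
              x$electrode_shift[1], x$electrode_shift[2]))
  for (nv in names(x$nerves)) {
    n <- x$nerves[[nv]]
    cat(sprintf("  %s: P1 %.1f ms/%.0f uV, N1 %.1f ms/%.0f uV, rate %.2f /ms, hotspot (%.2f, %.2f)\n",
                nv, n$p1_latency, n$p1_amplitude, n$n1_latency, n$n1_amplitude,
                n$hf_rate, n$hotspot["x"], n$hotspot["y"]))
  }
  invisible(x)
}

## Channel gains for one animal/nerve: exponential decay of each component
## with electrode-to-hotspot distance, electrode array displaced by the
## animal's shift (um -> mm).
channel_gains <- function(animal, nerve, layout = electrode_layout()) {
  hs <- animal$nerves[[nerve]]$hotspot
  ex <- layout$x + animal$electrode_shift[["lateral"]] / 1000
  ey <- layout$y + animal$electrode_shift[["rostrocaudal"]] / 1000
  d <- sqrt((ex - hs[["x"]])^2 + (ey - hs[["y"]])^2)
  exp(-d / animal$attenuation_length)
}
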