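# Shared fixtures, memoised so expensive transport runs happen once per
# test session no matter which files use them.

the_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(the_cache[[key]])) the_cache[[key]] <- force(expr)
  the_cache[[key]]
}

case1_medium <- function(family = "mhg") {
  medium(2, gamma = 1.5, mua = 0.2, family = family)
}

case2_medium <- function() medium(1, gamma = 1.9, mua = 0.2)

# a modest perpendicular case-1 run shared across files
case1_tally <- function() {
  memo("case1_tally", {
    simulate_probe(case1_medium(), probe_layout(seq(0.1, 1.0, by = 0.1)),
                   n_photons = 3e5, seed = 4242)
  })
}

case1_ws <- function() memo("case1_ws", ws_table(0.9, 0.85))

# hand-built tally exercising criterion/zv80 arithmetic without transport
synthetic_tally <- function(ps_w, depth_w = NULL, rho = 0.4,
                            depth_bin = 0.01) {
  nd <- ncol(ps_w)
  structure(list(
    reflectance = rep(1e-4, nd),
    batch_w = matrix(1, 10, nd),
    ps_w = ps_w, ps_n = ps_w,
    depth_w = depth_w, path_w = NULL,
    n_detected = colSums(ps_w),
    ledger = c(detected = sum(ps_w), escaped = 0, absorbed = 0, killed = 0,
               roulette_killed = 0, roulette_gain = 0),
    rho_mm = rep(rho, nd), tilt_deg = 0,
    n_photons = sum(ps_w), n_batches = 10, seed = 1,
    depth_bin_mm = depth_bin, path_bin_mm = 0.02,
    index_matched = TRUE, medium = NULL, layout = NULL),
    class = "detection_tally")
}

expect_within <- function(x, target, tol) {
  expect_lt(abs(x - target), tol)
}
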