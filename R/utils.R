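# internal utilities shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

## total order on sites: chromosome name (C locale), then position;
## every module may rely on this ordering
order_sites <- function(chrom, pos) order(chrom, pos, method = "radix")

## deterministic rounding: half away from zero, order-independent
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## derive a per-stage RNG stream from one master seed; result stays < 2^31
## so downstream set.seed() always receives a valid 32-bit integer
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 65521 + 1) * 16384 + offset %% 16384)
}

ec_log <- function(fmt, ...) message(sprintf(paste0("[epichannels] ", fmt), ...))
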