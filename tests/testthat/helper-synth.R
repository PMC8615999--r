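# Small stated-world configs used across tests: 1-s epochs, planted hub
# coupling at the default braking gain (2 x noise_sd) vs zero normal gain.
# Channel counts and fs are scaled down from 64 ch / 250 Hz to keep the
# default suite inside its CPU budget; the planted structure is unchanged.

small_cfg <- function(n_channels = 8, fs = 128, n_epochs_per_class = 8,
                      hub_channels = 1:3, noise_sd = 1,
                      coupling_gain = NULL, seed = 42) {
  synth_config(n_channels = n_channels, fs = fs, epoch_len = 1,
               n_epochs_per_class = n_epochs_per_class,
               hub_channels = hub_channels, coupling_gain = coupling_gain,
               noise_sd = noise_sd, seed = seed)
}

# Mean raw CsEn over hub-hub pairs of the given epochs.
hub_pair_mean <- function(es, hubs, params = csen_params()) {
  conns <- epoch_connectivity(es, params, normalize = FALSE)
  mean(vapply(conns, function(cm) {
    v <- cm$values[hubs, hubs]
    mean(v[row(v) != col(v)])
  }, numeric(1)))
}
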