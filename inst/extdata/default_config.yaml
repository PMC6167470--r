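# Default germinal-centre simulation: 21-day reaction, tamoxifen-decay
# staining at day 2 post GC onset with the measured 10-colour probabilities.
simulation:
  duration: 504      # hours (21 days)
  dt: 0.1            # hours
  founder_rate: 2    # founder cells per hour
  influx_window: 96  # influx limited to the first 4 days
staining:
  mode: decay
  scheme: tamoxifen10
  t_start: 48        # tamoxifen injection, hours post GC onset
  f_stained: 0.48    # one minus the black probability of the scheme
  tau_tamoxifen: 24  # decay time constant, hours
  tau_stainstop: 48  # staining switched off, hours after injection
  dt_stain: 1        # staining call interval, hours
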