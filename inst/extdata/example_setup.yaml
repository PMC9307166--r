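# Example configuration: three-axis square Helmholtz system of the
# reference setup. Lengths in meters, fields in microtesla. Separations
# omitted default to the homogeneity optimum (d/a ~ 0.545).
geometry:
  "x":
    shape: square
    size: 0.223
    turns: 32
    axis: [1, 0, 0]
    center: [0, 0, 0]
    polarity: serial
  "y":
    shape: square
    size: 0.400
    turns: 53
    axis: [0, 1, 0]
    center: [0, 0, 0]
    polarity: serial
  "z":
    shape: square
    size: 0.162
    turns: 19
    axis: [0, 0, 1]
    center: [0, 0, 0]
    polarity: serial
sensor:
  g_mag: 7.85        # nT per LSB
  noise_std: 0.54    # uT, 64x oversampling
  output_rate: 200   # Hz
driver:
  R_shunt: 1.0       # ohm
  control_divider: 1.0
  supply: 15         # V
  dropout: 4         # V
  current_limit: 3   # A
  coil_R: 10.1       # ohm (x pair)
  coil_L: 0.00105    # H (x pair)
  zeta: 0.517
ambient: [18.0, 0.0, -45.6]   # uT, a 49 uT field
seed: 20220722
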