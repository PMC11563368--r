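# Example run configuration.
#
# MSIC minor/major coefficients below are ILLUSTRATIVE PLACEHOLDERS for the
# linear-in-activity template F_thr = f_max * (c0 + c1 * a); replace them
# with the coefficients from the MSIC publication before drawing
# conclusions about a real model. The rupture threshold is always
# 3 * f_max and is not configurable.
muscles:
  - name: gastrocnemius_like
    f_max: 1558          # N
    l_ce_opt: 0.10       # m
    l_see_0: 0.361       # m
    tendon:
      family: TMM        # Thelen-type; default eps0 reproduces slope 0.52/%
  - name: stiff_positional_like
    pcsa: 11.1           # cm^2 -> f_max = pcsa * sigma_max
    sigma_max: 23        # N/cm^2
    l_ce_opt: 0.05
    l_see_0: 0.20
    tendon:
      family: EHTM       # extended-Hill-type; defaults give slope 0.24/%
boundary:
  pos_x: 2.9             # % strain, positional-tendon yield point
  pos_y: 1.92            # F/Fmax
  ens_x: 14.5            # % strain, energy-storage-tendon yield point
  ens_y: 0.96            # F/Fmax
msic:
  minor_c0: 1.0          # placeholder, see note above
  minor_c1: 0.0
  major_c0: 2.5          # placeholder, see note above
  major_c1: 0.0
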