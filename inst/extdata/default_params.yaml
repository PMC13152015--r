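Q_max:
  value: '340'
  unit: s^-1
theta:
  value: '12.9'
  unit: mV
sigma_prime:
  value: '3.7999999999999998'
  unit: mV
alpha:
  value: '60'
  unit: s^-1
beta:
  value: '240'
  unit: s^-1
gamma_e:
  value: '116'
  unit: s^-1
t0:
  value: '0.080000000000000002'
  unit: s
r_e:
  value: '0.085999999999999993'
  unit: m
phi_n:
  value: '100'
  unit: s^-1
nu_ee:
  value: '2.1141818181818186'
  unit: mV s
nu_ei:
  value: '-2.7406060606060607'
  unit: mV s
nu_er:
  value: '0'
  unit: mV s
nu_es:
  value: '0.78303030303030308'
  unit: mV s
nu_en:
  value: '-0.05867940854784752'
  unit: mV s
nu_ie:
  value: '2.1141818181818186'
  unit: mV s
nu_ii:
  value: '-2.7406060606060607'
  unit: mV s
nu_ir:
  value: '0'
  unit: mV s
nu_is:
  value: '0.78303030303030308'
  unit: mV s
nu_in:
  value: '-0.05867940854784752'
  unit: mV s
nu_re:
  value: '0.37103589743589738'
  unit: mV s
nu_ri:
  value: '0'
  unit: mV s
nu_rr:
  value: '0'
  unit: mV s
nu_rs:
  value: '0.15901538461538459'
  unit: mV s
nu_rn:
  value: '-0.048835346722543457'
  unit: mV s
nu_se:
  value: '0.74207179487179475'
  unit: mV s
nu_si:
  value: '0'
  unit: mV s
nu_sr:
  value: '-0.26502564102564102'
  unit: mV s
nu_ss:
  value: '0'
  unit: mV s
nu_sn:
  value: '-0.022332782619979348'
  unit: mV s
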