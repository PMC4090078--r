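{"p0":{"weights":[0.996,0.002,0.0020000000000000035],"total_mass":1},"q":{"weights":[0.33333333333333331,0.33333333333333331,0.33333333333333331],"total_mass":1},"epsilon":0.5,"step_hellinger":[0.10298692244425317,0.11906179186657141,0.099157375545459767,0.075997923020482805],"largest_change_step":2,"note":"deterministic lattice-search witness: the second persuasion changes the opinion more than the first"}
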