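{"epsilon_star":2.8095794634427866,"setup":"binary ignorant agent, certain opposed persuaders","note":"bisection-located recency-to-primacy crossover in the boomerang regime"}
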