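# Head-fixed acclimation (shaping) task
task_kind = "hf_shaping"
iti = 2.0
reward_volume_ul = 6.0
stimulus_duration = 6.0
auto_release_delay = 2.0

[session_end]
max_rewards = 125
max_duration_min = 90

[schedule]
n_trials = 400
labels = ["black", "white"]
probs = [0.5, 0.5]
max_consecutive = 400
seed = 1

[epochs.gate]
order = 1
name = "Gate"
trigger = "distance"
value = 20.0
stimulus = "gray"

[epochs.stimulus]
order = 2
name = "Stimulus"
trigger = "timer"
value = 6.0
stimulus = "black_or_white"

[contingency.black]
correct_side = "either"
reward_port = "licked"
volume_ul = 6.0

[contingency.white]
correct_side = "either"
reward_port = "licked"
volume_ul = 6.0

[adjustable]
side_bias_rule = true
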