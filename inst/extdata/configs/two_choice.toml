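# Head-fixed closed-loop two-choice visual discrimination task
task_kind = "two_choice_closed_loop"
iti = 2.0
reward_volume_ul = 6.0

[session_end]
max_rewards = 125
max_duration_min = 90

[schedule]
n_trials = 400
labels = ["vertical", "angled"]
probs = [0.5, 0.5]
max_consecutive = 3
seed = 1

[epochs.approach]
order = 1
name = "Approach"
trigger = "distance"
value = 50.0
stimulus = "circles"

[epochs.grating]
order = 2
name = "Grating"
trigger = "distance"
value = 50.0
stimulus = "per_trial"

[contingency.vertical]
correct_side = "left"
reward_port = "left"
volume_ul = 6.0

[contingency.angled]
correct_side = "right"
reward_port = "right"
volume_ul = 6.0

[stimulus_meta]
spatial_frequency_cpd = 0.04
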