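arm_id,ingredient_name,category,amount,country,cost_year,n_children
demo_home_visits,community_health_worker_time,workforce,1800,Alpha,2006,120
demo_home_visits,supervisor_time,workforce,600,Alpha,2006,120
demo_home_visits,picture_books,non_workforce,240,Alpha,2006,120
demo_home_visits,play_materials,non_workforce,360,Alpha,2006,120
demo_group_sessions,peer_educator_time,workforce,900,Alpha,2006,150
demo_group_sessions,session_materials,non_workforce,300,Alpha,2006,150
demo_centre_based,professional_educator_time,workforce,24000,Beta,2004,80
demo_centre_based,centre_rental,non_workforce,6000,Beta,2004,80
demo_centre_based,toys_and_books,non_workforce,2000,Beta,2004,80
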